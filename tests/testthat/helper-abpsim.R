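# Independent brute-force oracle for ABP stream semantics: enumerate every
# (cohort, payment-year) pair directly, no windowed summation.
brute_force_abp <- function(initiated, annuity, n, out_len) {
  values <- numeric(out_len)
  for (s in seq_along(initiated)) {       # cohort treated in year s-1
    for (k in 0:(n - 1L)) {               # owes annuity k years later
      yr <- (s - 1L) + k
      if (yr < out_len) values[yr + 1L] <- values[yr + 1L] +
          annuity * initiated[s]
    }
  }
  values
}

# Build a treated_flow from a raw initiation vector (all incident, no backlog)
make_flow <- function(initiated) {
  structure(
    list(horizon_years = length(initiated),
         initiated = as.numeric(initiated),
         backlog_component = numeric(length(initiated)),
         incident_component = as.numeric(initiated)),
    class = "treated_flow"
  )
}

lca_epi <- function(...) {
  epi_spec(prevalence_rate = 1 / 10700, incidence_rate = 1 / 750000,
           incidence_basis = "births", ...)
}

dlbcl_epi <- function(...) {
  epi_spec(prevalence_rate = 1.25e-5, incidence_rate = 2.5e-5,
           incidence_basis = "population", disease_duration_years = 0.5, ...)
}
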