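#' Disease and population parameters for the treated-patient projection
#'
#' Bundles the epidemiological inputs that drive how many patients start the
#' one-time therapy each year: a prevalent backlog waiting at launch plus a
#' yearly incident inflow growing at demographic factor `g`. Prevalence is
#' always a fraction of the total population; incidence may be expressed per
#' head of population or per newborn (`incidence_basis`), since rare
#' congenital diseases are usually quoted per birth.
#'
#' A consistency warning (not an error) is emitted when a disease duration is
#' supplied on the population basis and prevalence departs from
#' incidence x duration by more than 5\%: for a stationary disease the
#' prevalent pool should equal the yearly inflow times how long patients
#' remain prevalent.
#'
#' @param prevalence_rate Fraction of the population alive with the disease at
#'   launch (the backlog source).
#' @param incidence_rate New cases per year, as a fraction of
#'   `incidence_basis`.
#' @param incidence_basis `"population"` or `"births"`.
#' @param population_size,births_per_year Reference demography. Defaults are
#'   a Belgian-scale population of 11.5 million with 120,000 births/yr; the
#'   feasibility ratios downstream are invariant to joint rescaling.
#' @param growth_rate Yearly growth factor `g` of the incident inflow, in
#'   `[-0.05, 0.05]`.
#' @param backlog_spread_years Number of initial years `m` over which the
#'   prevalent backlog is treated (equal shares); integer, at least 1.
#' @param disease_duration_years Mean years a case remains prevalent; used
#'   only for the consistency check. `NA` to skip.
#' @param uptake_fraction Fraction of eligible patients actually treated,
#'   in (0, 1].
#' @return An object of class `epi_spec` (validated list).
#' @examples
#' lca <- epi_spec(prevalence_rate = 1 / 10700, incidence_rate = 1 / 750000,
#'                 incidence_basis = "births")
#' classify_dominance(lca)
#' @export
epi_spec <- function(prevalence_rate,
                     incidence_rate,
                     incidence_basis = c("population", "births"),
                     population_size = 11.5e6,
                     births_per_year = 120000,
                     growth_rate = 0,
                     backlog_spread_years = 1,
                     disease_duration_years = NA_real_,
                     uptake_fraction = 1) {
  incidence_basis <- match.arg(incidence_basis)
  check_number(prevalence_rate, "prevalence_rate", lower = 0, upper = 1)
  check_number(incidence_rate, "incidence_rate", lower = 0, upper = 1)
  check_number(population_size, "population_size", lower = 0, strict_lower = TRUE)
  check_number(births_per_year, "births_per_year", lower = 0, strict_lower = TRUE)
  check_number(growth_rate, "growth_rate", lower = -0.05, upper = 0.05)
  check_number(backlog_spread_years, "backlog_spread_years",
               lower = 1, integer = TRUE)
  check_number(uptake_fraction, "uptake_fraction",
               lower = 0, upper = 1, strict_lower = TRUE)
  if (!is.na(disease_duration_years)) {
    check_number(disease_duration_years, "disease_duration_years",
                 lower = 0, strict_lower = TRUE)
  }
  spec <- structure(
    list(
      prevalence_rate = prevalence_rate,
      incidence_rate = incidence_rate,
      incidence_basis = incidence_basis,
      population_size = population_size,
      births_per_year = births_per_year,
      growth_rate = growth_rate,
      backlog_spread_years = as.integer(backlog_spread_years),
      disease_duration_years = disease_duration_years,
      uptake_fraction = uptake_fraction
    ),
    class = "epi_spec"
  )
  # stationarity check prev ~ inc * duration only applies when both rates
  # share the population denominator
  if (!is.na(disease_duration_years) && incidence_basis == "population" &&
      prevalence_rate > 0) {
    implied <- incidence_rate * disease_duration_years
    if (abs(implied - prevalence_rate) > 0.05 * prevalence_rate) {
      warning(sprintf(
        paste0("prevalence_rate (%.3g) differs from incidence_rate x ",
               "disease_duration (%.3g); check the epidemiology inputs"),
        prevalence_rate, implied), call. = FALSE)
    }
  }
  spec
}

#' @export
print.epi_spec <- function(x, ...) {
  cat("Epidemiology spec\n")
  cat(sprintf("  prevalence: %.4g of population (%.1f patients)\n",
              x$prevalence_rate, prevalent_count(x)))
  cat(sprintf("  incidence:  %.4g per %s (%.2f patients/yr), growth %.1f%%/yr\n",
              x$incidence_rate, x$incidence_basis, incident_count(x),
              100 * x$growth_rate))
  cat(sprintf("  backlog spread m = %d yr, uptake %.0f%%\n",
              x$backlog_spread_years, 100 * x$uptake_fraction))
  invisible(x)
}

#' Absolute prevalent backlog and first-year incident counts
#'
#' `prevalent_count()` is the number of patients waiting at launch
#' (prevalence x population); `incident_count()` is the year-0 incident
#' inflow (incidence x population or x births, per the spec's basis).
#' Uptake is *not* applied here; [patient_flow()] applies it.
#'
#' @param spec An [epi_spec()].
#' @return A single patient count (real-valued; the model is an expected-value
#'   cohort model, so fractional patients are meaningful).
#' @export
prevalent_count <- function(spec) {
  spec$prevalence_rate * spec$population_size
}

#' @rdname prevalent_count
#' @export
incident_count <- function(spec) {
  base <- switch(spec$incidence_basis,
                 population = spec$population_size,
                 births = spec$births_per_year)
  spec$incidence_rate * base
}

#' Yearly flow of newly treated patients over the horizon
#'
#' Projects how many patients *start* the one-time therapy in each model year:
#' the prevalent backlog is treated in equal shares over the first `m` years,
#' and the incident cohort of year `t` is `inc0 * (1+g)^t`, both scaled by the
#' uptake fraction. The model is deterministic and real-valued (expected
#' counts, no stochastic rounding).
#'
#' @param spec An [epi_spec()].
#' @param horizon Number of model years `T` (year indices `0 .. T-1`).
#' @return An object of class `treated_flow`: list with `horizon_years`,
#'   `initiated` (length-`T` vector of starts per year) and its additive parts
#'   `backlog_component` and `incident_component`.
#' @examples
#' sp <- epi_spec(prevalence_rate = 1e-5, incidence_rate = 2e-6,
#'                backlog_spread_years = 2)
#' patient_flow(sp, 10)
#' @export
patient_flow <- function(spec, horizon) {
  check_number(horizon, "horizon", lower = 1, integer = TRUE)
  horizon <- as.integer(horizon)
  m <- spec$backlog_spread_years
  if (m > horizon) {
    stop_invalid(sprintf(
      "backlog_spread_years (%d) exceeds the model horizon (%d)", m, horizon))
  }
  u <- spec$uptake_fraction
  backlog <- numeric(horizon)
  backlog[seq_len(m)] <- prevalent_count(spec) * u / m
  t <- seq_len(horizon) - 1
  incident <- incident_count(spec) * (1 + spec$growth_rate)^t * u
  structure(
    list(
      horizon_years = horizon,
      initiated = backlog + incident,
      backlog_component = backlog,
      incident_component = incident
    ),
    class = "treated_flow"
  )
}

#' @export
print.treated_flow <- function(x, ...) {
  cat(sprintf("Treated-patient flow over %d years: %.1f patients total\n",
              x$horizon_years, sum(x$initiated)))
  cat(sprintf("  backlog %.1f, incident %.1f; first years: %s ...\n",
              sum(x$backlog_component), sum(x$incident_component),
              paste(round(utils::head(x$initiated, 5), 2), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.treated_flow <- function(x, ...) {
  data.frame(
    year = seq_len(x$horizon_years) - 1L,
    initiated = x$initiated,
    backlog = x$backlog_component,
    incident = x$incident_component
  )
}

#' Classify a disease as prevalence- or incidence-dominant
#'
#' A disease is prevalence-dominant when the backlog of patients waiting at
#' launch exceeds the yearly inflow of new cases (ratio of prevalent count to
#' first-year incident count strictly greater than 1); otherwise it is
#' incidence-dominant. The boundary ratio of exactly 1 counts as
#' incidence-dominant.
#'
#' @param spec An [epi_spec()].
#' @return `"prevalence_dominant"` or `"incidence_dominant"`.
#' @export
classify_dominance <- function(spec) {
  prev <- prevalent_count(spec)
  inc0 <- incident_count(spec)
  if (inc0 == 0 && prev == 0) {
    stop_invalid("cannot classify dominance: prevalence and incidence both zero")
  }
  if (inc0 == 0 || prev / inc0 > 1) "prevalence_dominant" else "incidence_dominant"
}
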