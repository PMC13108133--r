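#' Packaged disease scenario presets
#'
#' Two presets ship with the package, spanning the two epidemiological
#' regimes that matter for annuity-based payment:
#' \describe{
#'   \item{`"lca"`}{Leber congenital amaurosis treated by one-time gene
#'     therapy — prevalence-dominant: a large backlog of prevalent patients
#'     (prevalence 1/10,700 of the population) against a tiny incident inflow
#'     (1/750,000 newborns); price EUR 1m, yearly budget cap EUR 250m,
#'     durability taken as the 75-year envisaged lifetime.}
#'   \item{`"dlbcl"`}{Diffuse large B-cell lymphoma treated by CAR-T —
#'     incidence-dominant: rapid mortality leaves almost no backlog
#'     (prevalence 1.25/100,000 vs incidence 2.5/100,000 per year, a
#'     0.5-year duration); price EUR 350k, cap EUR 10m, durability about
#'     2.5 years.}
#' }
#'
#' @param name `"lca"` or `"dlbcl"`.
#' @return A `scenario_config` (see [load_config()]).
#' @examples
#' abp_preset("lca")$price
#' @export
abp_preset <- function(name) {
  available <- abp_presets()
  if (!is.character(name) || length(name) != 1L || !(name %in% available)) {
    stop_config(sprintf("unknown preset '%s'; available presets: %s",
                        paste(name, collapse = ","),
                        paste(available, collapse = ", ")))
  }
  load_config(system.file("extdata", paste0(name, ".yaml"),
                          package = "abpsim", mustWork = TRUE))
}

#' @rdname abp_preset
#' @export
abp_presets <- function() {
  sort(sub("\\.yaml$", "",
           dir(system.file("extdata", package = "abpsim"),
               pattern = "\\.yaml$")))
}

#' Default bond-type x maturity scheme grid
#'
#' The six financing schemes evaluated throughout: a health impact bond
#' (default 3\%, the top of its 1--3\% range) and a corporate bond (default
#' 10\%, the top of its 8--10\% range), each at 5-, 10- and 15-year maturity.
#'
#' @param price Upfront price per patient.
#' @param health_rate,corporate_rate Bond rates as fractions.
#' @param maturities Integer vector of annuity counts.
#' @return A list of [payment_scheme()]s, health impact bonds first.
#' @export
default_scheme_grid <- function(price, health_rate = 0.03,
                                corporate_rate = 0.10,
                                maturities = c(5L, 10L, 15L)) {
  c(
    lapply(maturities, function(n) {
      payment_scheme(price, n_payments = n, bond_rate = health_rate,
                     bond_type = "health_impact")
    }),
    lapply(maturities, function(n) {
      payment_scheme(price, n_payments = n, bond_rate = corporate_rate,
                     bond_type = "corporate")
    })
  )
}

report_row <- function(scheme, rep) {
  cbind(
    data.frame(bond_type = scheme$bond_type,
               bond_rate = scheme$bond_rate,
               maturity_years = scheme$n_payments),
    summary(rep)[, setdiff(names(summary(rep)), "scheme_label")]
  )
}

empty_report <- function() {
  data.frame(
    bond_type = character(), bond_rate = numeric(),
    maturity_years = integer(), c1_pass = logical(),
    c2a_ratio = numeric(), c2a_pass = logical(),
    c2b_ratio = numeric(), c2b_pass = logical(),
    c3_ratio = numeric(), c3_pass = logical(),
    c4_pass = logical(), overall_feasible = logical()
  )
}

#' Evaluate a preset across a grid of payment schemes
#'
#' Runs the four-condition screen for every scheme in the grid against one
#' disease preset, producing one report row per (bond type, maturity) in the
#' shape of the published feasibility tables.
#'
#' @param name Preset name, see [abp_preset()].
#' @param scheme_grid List of [payment_scheme()]s; default is the
#'   [default_scheme_grid()] at the preset's price. An empty list yields an
#'   empty report.
#' @param policy Truncation policy for the ABP streams.
#' @return A data.frame with columns `bond_type`, `bond_rate`,
#'   `maturity_years`, the condition ratios and pass flags, and
#'   `overall_feasible`.
#' @examples
#' run_preset("lca")
#' @export
run_preset <- function(name, scheme_grid = NULL, policy = truncation_policy()) {
  cfg <- abp_preset(name)
  if (is.null(scheme_grid)) {
    scheme_grid <- if (length(cfg$schemes)) cfg$schemes else
      default_scheme_grid(cfg$price)
  }
  if (!length(scheme_grid)) return(empty_report())
  flow <- patient_flow(cfg$epidemiology, cfg$economics$horizon_years)
  rows <- lapply(scheme_grid, function(sch) {
    report_row(sch, evaluate_conditions(flow, sch, cfg$economics,
                                        cfg$durability_years, policy))
  })
  do.call(rbind, rows)
}

sweep_axes <- c("bond_rate", "n_payments", "backlog_spread_years",
                "growth_rate", "price", "prev_inc_ratio")

modify_epi <- function(epi, ...) {
  fields <- list(...)
  args <- unclass(epi)
  args[names(fields)] <- fields
  do.call(epi_spec, args)
}

#' Sweep scenario parameters over a feasibility grid
#'
#' Evaluates the four-condition screen over the Cartesian product of one or
#' more parameter grids, holding the rest of the base scenario fixed. The
#' admissible axes are `bond_rate`, `n_payments`, `backlog_spread_years`,
#' `growth_rate`, `price` and `prev_inc_ratio` (the prevalent-backlog to
#' first-year-incidence ratio, varied by rescaling prevalence at fixed
#' incidence). Grid order is deterministic: the first axis varies fastest.
#'
#' @param base A `scenario_config` (from [abp_preset()] or [load_config()]);
#'   its first scheme is the base payment scheme.
#' @param axes Named list of numeric grids; each grid must be non-empty,
#'   finite and strictly increasing.
#' @param policy Truncation policy for the ABP streams.
#' @return A long-format data.frame: one row per grid point with the axis
#'   values followed by the condition report columns.
#' @examples
#' grid <- feasibility_sweep(abp_preset("lca"),
#'                           list(backlog_spread_years = 1:5))
#' grid[, c("backlog_spread_years", "overall_feasible")]
#' @export
feasibility_sweep <- function(base, axes, policy = truncation_policy()) {
  if (!length(axes) || is.null(names(axes)) || any(names(axes) == "")) {
    stop_invalid("'axes' must be a non-empty named list of grids")
  }
  bad <- setdiff(names(axes), sweep_axes)
  if (length(bad)) {
    stop_invalid(sprintf("unknown sweep axis: %s (admissible: %s)",
                         paste(bad, collapse = ", "),
                         paste(sweep_axes, collapse = ", ")))
  }
  for (nm in names(axes)) {
    g <- axes[[nm]]
    if (!length(g) || !is.numeric(g) || any(!is.finite(g))) {
      stop_invalid(sprintf("grid for '%s' must be non-empty and finite", nm))
    }
    if (length(g) > 1 && any(diff(g) <= 0)) {
      stop_invalid(sprintf("grid for '%s' must be strictly increasing", nm))
    }
  }
  pts <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  base_scheme <- if (length(base$schemes)) base$schemes[[1]] else
    payment_scheme(base$price, n_payments = 10, bond_rate = 0.03)
  rows <- lapply(seq_len(nrow(pts)), function(k) {
    p <- pts[k, , drop = FALSE]
    epi <- base$epidemiology
    sch_args <- list(price = base_scheme$price,
                     n_payments = base_scheme$n_payments,
                     bond_rate = base_scheme$bond_rate,
                     bond_type = base_scheme$bond_type)
    for (nm in names(p)) {
      v <- p[[nm]]
      if (nm == "bond_rate") sch_args$bond_rate <- v
      if (nm == "n_payments") sch_args$n_payments <- v
      if (nm == "price") sch_args$price <- v
      if (nm == "backlog_spread_years") {
        epi <- modify_epi(epi, backlog_spread_years = v)
      }
      if (nm == "growth_rate") epi <- modify_epi(epi, growth_rate = v)
      if (nm == "prev_inc_ratio") {
        prev <- v * incident_count(epi) / epi$population_size
        epi <- modify_epi(epi, prevalence_rate = prev)
      }
    }
    scheme <- do.call(payment_scheme, sch_args)
    flow <- patient_flow(epi, base$economics$horizon_years)
    rep <- evaluate_conditions(flow, scheme, base$economics,
                               base$durability_years, policy)
    cbind(p, summary(rep)[, setdiff(names(summary(rep)), "scheme_label")],
          row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Largest bond rate keeping ABP cost-equivalent with upfront payment
#'
#' Sweeps the bond rate over a grid and returns the largest rate at which
#' Condition 2a (NPV cost-equivalence at the social discount rate `r`) still
#' passes. Under full-ledger semantics every patient's annuity schedule has
#' NPV equal to the price at the bond rate, so the threshold equals `r`
#' analytically and is independent of the therapy price; window truncation
#' can admit slightly higher rates because payments outside the horizon are
#' never billed.
#'
#' @param base A `scenario_config`; its first scheme fixes the maturity.
#' @param rate_grid Strictly increasing grid of bond rates; for the threshold
#'   to be informative it should span the social discount rate.
#' @param policy Truncation policy; default `"full_ledger"` (the analytic
#'   setting).
#' @return The largest passing rate, or `NA_real_` (with a warning) when no
#'   grid rate passes.
#' @examples
#' rate_threshold(abp_preset("lca"), seq(0, 0.06, by = 0.01))
#' @export
rate_threshold <- function(base, rate_grid,
                           policy = truncation_policy("full_ledger")) {
  if (!length(rate_grid) || !is.numeric(rate_grid) ||
      any(!is.finite(rate_grid))) {
    stop_invalid("'rate_grid' must be a non-empty finite numeric grid")
  }
  if (length(rate_grid) > 1 && any(diff(rate_grid) <= 0)) {
    stop_invalid("'rate_grid' must be strictly increasing")
  }
  r <- base$economics$social_discount_rate
  base_scheme <- if (length(base$schemes)) base$schemes[[1]] else
    payment_scheme(base$price, n_payments = 10, bond_rate = r)
  flow <- patient_flow(base$epidemiology, base$economics$horizon_years)
  up_nom <- build_upfront_stream(flow, base_scheme$price)
  tol <- 1e-9
  passing <- vapply(rate_grid, function(i) {
    sch <- payment_scheme(base_scheme$price,
                          n_payments = base_scheme$n_payments,
                          bond_rate = i, bond_type = base_scheme$bond_type)
    ab_nom <- build_abp_stream(flow, sch, policy)
    condition2a(up_nom, ab_nom, r) <= 1 + tol
  }, logical(1))
  if (!any(passing)) {
    warning("no rate in the grid satisfies Condition 2a", call. = FALSE)
    return(NA_real_)
  }
  max(rate_grid[passing])
}
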