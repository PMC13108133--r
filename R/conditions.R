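#' Economic parameters of the budget-impact evaluation
#'
#' @param budget_cap Maximum tolerable net yearly budget impact `BI_max` for
#'   the indication (currency/yr), positive.
#' @param social_discount_rate Social rate of time preference `r` used to
#'   discount future public expenditure; fraction/yr in `[0, 0.15]`,
#'   default 3\%.
#' @param inflation_rate Constant yearly inflation applied to nominal streams
#'   before discounting; default 0 (streams in real terms).
#' @param horizon_years Evaluation horizon `T` in years, default 25.
#' @return An object of class `econ_spec`.
#' @export
econ_spec <- function(budget_cap,
                      social_discount_rate = 0.03,
                      inflation_rate = 0,
                      horizon_years = 25) {
  check_number(budget_cap, "budget_cap", lower = 0, strict_lower = TRUE)
  check_number(social_discount_rate, "social_discount_rate",
               lower = 0, upper = 0.15)
  check_number(inflation_rate, "inflation_rate", lower = -0.05, upper = 0.25)
  check_number(horizon_years, "horizon_years", lower = 1, integer = TRUE)
  structure(
    list(budget_cap = budget_cap,
         social_discount_rate = social_discount_rate,
         inflation_rate = inflation_rate,
         horizon_years = as.integer(horizon_years)),
    class = "econ_spec"
  )
}

#' @export
print.econ_spec <- function(x, ...) {
  cat(sprintf(
    "Economic spec: cap %s/yr, r = %.1f%%, inflation %.1f%%, horizon %d y\n",
    fmt_eur(x$budget_cap), 100 * x$social_discount_rate,
    100 * x$inflation_rate, x$horizon_years))
  invisible(x)
}

apply_inflation <- function(stream, rate) {
  if (rate == 0) return(stream)
  t <- seq_along(stream$values) - 1
  cashflow_stream(stream$values * (1 + rate)^t, basis = stream$basis,
                  scheme_label = stream$scheme_label)
}

#' Condition 1: the cap must bite upfront but not under ABP
#'
#' Annuities are only justified when the upfront bill breaches the payer's
#' yearly budget cap while the spread payments stay within it. Both streams
#' must already be discounted at the social rate; the cap itself is a fixed
#' yearly amount and is not discounted.
#'
#' @param upfront,abp Discounted [cashflow_stream]s for the two schemes.
#' @param econ An [econ_spec()] supplying `budget_cap`.
#' @return A list with logicals `upfront_exceeds_cap`, `abp_within_cap` and
#'   their conjunction `pass`.
#' @export
condition1 <- function(upfront, abp, econ) {
  check_flag_basis(upfront, "discounted", "upfront")
  check_flag_basis(abp, "discounted", "abp")
  up <- max(upfront$values) > econ$budget_cap
  ab <- max(abp$values) <= econ$budget_cap
  list(upfront_exceeds_cap = up, abp_within_cap = ab, pass = up && ab)
}

#' Condition 2a: NPV cost-equivalence over the horizon
#'
#' The socially discounted total cost of the ABP stream must not exceed that
#' of upfront payment: the ratio `NPV(abp, r) / NPV(upfront, r)` must be at
#' most 1. Takes nominal streams and discounts inside, so the two NPVs use
#' the same convention even when the ABP ledger extends past the payer
#' horizon.
#'
#' @param upfront,abp Nominal [cashflow_stream]s starting at year 0 (the ABP
#'   stream may be longer under a full-ledger policy).
#' @param r Social discount rate, fraction/yr.
#' @return The NPV ratio (dimensionless).
#' @export
condition2a <- function(upfront, abp, r) {
  check_flag_basis(upfront, "nominal", "upfront")
  check_flag_basis(abp, "nominal", "abp")
  denom <- npv(upfront, r)
  if (denom == 0) stop_invalid("upfront stream has zero NPV")
  npv(abp, r) / denom
}

#' Condition 2b: maximum-yearly-budget non-exceedance
#'
#' The stricter reading of cost-equivalence: in no year may the ABP bill top
#' the worst upfront year. Computed as the ratio of the maxima of the two
#' discounted yearly streams, `BI_A,Max / BI_U,Max`; at most 1 is preferred.
#'
#' @param upfront,abp Discounted [cashflow_stream]s.
#' @return The ratio of yearly maxima (dimensionless).
#' @export
condition2b <- function(upfront, abp) {
  check_flag_basis(upfront, "discounted", "upfront")
  check_flag_basis(abp, "discounted", "abp")
  denom <- max(upfront$values)
  if (denom == 0) stop_invalid("upfront stream has zero maximum")
  max(abp$values) / denom
}

#' Condition 3: manufacturer compensation for financial risk
#'
#' The manufacturer accepts the spread payments only if their value matches
#' the negotiated upfront price. Two metrics are reported:
#' `"npv_at_bond_rate"` — the NPV of the annuity schedule at the bond rate
#' divided by the principal, which the annuity-due construction makes exactly
#' 1 (reported for audit); and `"nominal_sum"` — the undiscounted total
#' `n * A / P`, i.e. the premium the payer concedes in exchange for spreading.
#' The condition passes when the chosen ratio is at least 1.
#'
#' @param scheme A [payment_scheme()] with annuity modality.
#' @param metric `"npv_at_bond_rate"` (default) or `"nominal_sum"`.
#' @return The ratio (dimensionless).
#' @export
condition3 <- function(scheme, metric = c("npv_at_bond_rate", "nominal_sum")) {
  metric <- match.arg(metric)
  if (!inherits(scheme, "payment_scheme") || scheme$modality != "annuity") {
    stop_invalid("'scheme' must be a payment_scheme with modality 'annuity'")
  }
  sched <- annuity_due(scheme$price, scheme$bond_rate, scheme$n_payments)
  switch(metric,
    npv_at_bond_rate = npv(sched, scheme$bond_rate) / sched$principal,
    nominal_sum = sched$n_payments * sched$annuity_amount / sched$principal
  )
}

#' Condition 4: the annuity period must respect durability of effect
#'
#' Paying in instalments for a one-time therapy is defensible only while its
#' effect is credibly sustained: the number of annuities may not exceed the
#' measured durability (whole years).
#'
#' @param scheme A [payment_scheme()].
#' @param durability_years Durability of the therapeutic effect in years,
#'   positive (may be fractional, e.g. 2.5).
#' @return `TRUE` if `n_payments <= floor(durability_years)`.
#' @export
condition4 <- function(scheme, durability_years) {
  check_number(durability_years, "durability_years",
               lower = 0, strict_lower = TRUE)
  scheme$n_payments <= floor(durability_years)
}

#' Evaluate all four ABP feasibility conditions for one scenario
#'
#' Assembles the upfront and ABP budget-impact streams for a treated-patient
#' flow, applies inflation (if any) and social discounting, and screens the
#' four acceptability conditions: (1) the cap bites upfront but not under
#' ABP; (2a) NPV cost-equivalence and (2b) maximum-yearly non-exceedance;
#' (3) manufacturer risk compensation; (4) annuity count within durability.
#' A scheme is feasible overall only when all four pass. The evaluation is a
#' pure function of its inputs: repeated calls are bit-identical.
#'
#' @param flow A [patient_flow()] result; its horizon must equal
#'   `econ$horizon_years`.
#' @param scheme A [payment_scheme()] with annuity modality.
#' @param econ An [econ_spec()].
#' @param durability_years Durability of effect in years.
#' @param policy A [truncation_policy()] or its mode string; default
#'   `"window_only"` (payer budget perspective).
#' @param c3_metric Metric for Condition 3, see [condition3()].
#' @return An object of class `condition_report`: pass flags and ratio
#'   metrics for every condition, `overall_feasible`, and the discounted
#'   streams (for plotting).
#' @examples
#' cfg <- abp_preset("lca")
#' fl <- patient_flow(cfg$epidemiology, cfg$economics$horizon_years)
#' evaluate_conditions(fl, payment_scheme(cfg$price, n_payments = 10,
#'                                        bond_rate = 0.03),
#'                     cfg$economics, cfg$durability_years)
#' @export
evaluate_conditions <- function(flow, scheme, econ, durability_years,
                                policy = truncation_policy(),
                                c3_metric = c("npv_at_bond_rate", "nominal_sum")) {
  c3_metric <- match.arg(c3_metric)
  policy <- as_truncation(policy)
  if (flow$horizon_years != econ$horizon_years) {
    stop_invalid(sprintf("flow horizon (%d) must equal econ horizon (%d)",
                         flow$horizon_years, econ$horizon_years))
  }
  r <- econ$social_discount_rate
  up_nom <- apply_inflation(build_upfront_stream(flow, scheme$price),
                            econ$inflation_rate)
  ab_nom <- apply_inflation(build_abp_stream(flow, scheme, policy),
                            econ$inflation_rate)
  up_dis <- discount_stream(up_nom, r)
  ab_dis <- discount_stream(ab_nom, r)

  c1 <- condition1(up_dis, ab_dis, econ)
  c2a_ratio <- condition2a(up_nom, ab_nom, r)
  c2b_ratio <- condition2b(up_dis, ab_dis)
  c3_ratio <- condition3(scheme, c3_metric)
  c4_pass <- condition4(scheme, durability_years)

  tol <- 1e-9 # ratios of exactly 1 count as pass ("no greater than")
  rep <- list(
    scheme_label = scheme$label,
    c1_upfront_exceeds_cap = c1$upfront_exceeds_cap,
    c1_abp_within_cap = c1$abp_within_cap,
    c1_pass = c1$pass,
    c2a_ratio = c2a_ratio,
    c2a_pass = c2a_ratio <= 1 + tol,
    c2b_ratio = c2b_ratio,
    c2b_pass = c2b_ratio <= 1 + tol,
    c3_ratio = c3_ratio,
    c3_metric = c3_metric,
    c3_pass = c3_ratio >= 1 - tol,
    c4_n_max = as.integer(floor(durability_years)),
    c4_pass = c4_pass,
    streams = list(upfront = up_dis, abp = ab_dis, budget_cap = econ$budget_cap)
  )
  rep$overall_feasible <- rep$c1_pass && rep$c2a_pass && rep$c2b_pass &&
    rep$c3_pass && rep$c4_pass
  structure(rep, class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  flag <- function(p) if (p) "pass" else "FAIL"
  cat(sprintf("ABP feasibility report — scheme %s\n", x$scheme_label))
  cat(sprintf("  C1  budget cap:      %s (upfront exceeds: %s, ABP within: %s)\n",
              flag(x$c1_pass), x$c1_upfront_exceeds_cap, x$c1_abp_within_cap))
  cat(sprintf("  C2a NPV equivalence: %s (ratio %.4f)\n",
              flag(x$c2a_pass), x$c2a_ratio))
  cat(sprintf("  C2b max yearly BI:   %s (ratio %.4f)\n",
              flag(x$c2b_pass), x$c2b_ratio))
  cat(sprintf("  C3  manufacturer:    %s (%s = %.4f)\n",
              flag(x$c3_pass), x$c3_metric, x$c3_ratio))
  cat(sprintf("  C4  durability:      %s (n_max %d)\n",
              flag(x$c4_pass), x$c4_n_max))
  cat(sprintf("  Overall feasible:    %s\n",
              if (x$overall_feasible) "YES" else "no"))
  invisible(x)
}

#' @export
summary.condition_report <- function(object, ...) {
  data.frame(
    scheme_label = object$scheme_label,
    c1_pass = object$c1_pass,
    c2a_ratio = object$c2a_ratio, c2a_pass = object$c2a_pass,
    c2b_ratio = object$c2b_ratio, c2b_pass = object$c2b_pass,
    c3_ratio = object$c3_ratio, c3_pass = object$c3_pass,
    c4_pass = object$c4_pass,
    overall_feasible = object$overall_feasible
  )
}

#' @export
plot.condition_report <- function(x, ...) {
  up <- x$streams$upfront
  ab <- x$streams$abp
  yrs_u <- seq_len(up$horizon_years) - 1L
  yrs_a <- seq_len(ab$horizon_years) - 1L
  ylim <- range(0, up$values, ab$values, x$streams$budget_cap)
  graphics::plot(yrs_u, up$values, type = "s", ylim = ylim,
                 xlab = "model year", ylab = "discounted budget impact",
                 main = x$scheme_label, ...)
  graphics::lines(yrs_a, ab$values, type = "s", lty = 2)
  graphics::abline(h = x$streams$budget_cap, lty = 3)
  graphics::legend("topright", lty = c(1, 2, 3), bty = "n",
                   legend = c("upfront", "ABP", "budget cap"))
  invisible(x)
}
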