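#' Payment scheme for a one-time therapy
#'
#' Describes how the payer funds each treated patient: either a single upfront
#' lump sum, or an annuity-based payment (ABP) of `n_payments` yearly
#' annuities financed at `bond_rate`. The bond type records who issues the
#' financing instrument: a governmental health impact bond (low rate) or a
#' corporate bond placed by the manufacturer (higher rate).
#'
#' @param price Negotiated upfront price per patient (currency), positive.
#' @param modality `"annuity"` or `"upfront"`. Upfront is represented as a
#'   single payment with a zero rate.
#' @param n_payments Number of yearly annuities `n` (ignored for upfront).
#' @param bond_rate Financing rate `i` as a fraction (ignored for upfront).
#' @param bond_type `"health_impact"` or `"corporate"`; informational label.
#' @param label Optional scheme label used in stream exports; a readable
#'   default is derived from the other fields.
#' @return An object of class `payment_scheme`.
#' @examples
#' payment_scheme(1e6, n_payments = 10, bond_rate = 0.03)
#' @export
payment_scheme <- function(price,
                           modality = c("annuity", "upfront"),
                           n_payments = 1,
                           bond_rate = 0,
                           bond_type = c("health_impact", "corporate"),
                           label = NULL) {
  modality <- match.arg(modality)
  bond_type <- match.arg(bond_type)
  check_number(price, "price", lower = 0, strict_lower = TRUE)
  if (modality == "upfront") {
    n_payments <- 1
    bond_rate <- 0
  }
  check_number(n_payments, "n_payments", lower = 1, integer = TRUE)
  check_number(bond_rate, "bond_rate", lower = 0)
  if (is.null(label)) {
    label <- if (modality == "upfront") "upfront" else
      sprintf("%s_%g%%_%dy", bond_type, 100 * bond_rate, as.integer(n_payments))
  }
  structure(
    list(price = price, modality = modality,
         n_payments = as.integer(n_payments), bond_rate = bond_rate,
         bond_type = bond_type, label = label),
    class = "payment_scheme"
  )
}

#' @export
print.payment_scheme <- function(x, ...) {
  if (x$modality == "upfront") {
    cat(sprintf("Upfront payment scheme: %s per patient\n", fmt_eur(x$price)))
  } else {
    cat(sprintf(
      "ABP scheme: %s per patient as %d annuities at %.2f%% (%s bond)\n",
      fmt_eur(x$price), x$n_payments, 100 * x$bond_rate, x$bond_type))
  }
  invisible(x)
}

#' Horizon-truncation policy for ABP streams
#'
#' Under `"window_only"` (the payer's budget perspective) annuities falling
#' after the model horizon are dropped from the stream; under `"full_ledger"`
#' the stream is extended so every contracted payment appears (the
#' manufacturer's contract view).
#'
#' @param mode `"window_only"` or `"full_ledger"`.
#' @return An object of class `truncation_policy`.
#' @export
truncation_policy <- function(mode = c("window_only", "full_ledger")) {
  mode <- match.arg(mode)
  structure(list(mode = mode), class = "truncation_policy")
}

as_truncation <- function(policy) {
  if (inherits(policy, "truncation_policy")) return(policy)
  truncation_policy(policy)
}

#' Yearly payer budget-impact stream
#'
#' A time series of yearly payer expenditure (currency/yr), indexed from model
#' year 0, on either the nominal or the discounted basis. Usually built via
#' [build_upfront_stream()] / [build_abp_stream()] rather than directly.
#'
#' @param values Non-negative numeric vector, one entry per model year.
#' @param basis `"nominal"` or `"discounted"`.
#' @param scheme_label Free-text label carried into exports.
#' @return An object of class `cashflow_stream`.
#' @export
cashflow_stream <- function(values, basis = c("nominal", "discounted"),
                            scheme_label = "") {
  basis <- match.arg(basis)
  if (!is.numeric(values) || anyNA(values)) {
    stop_invalid("stream values must be numeric and non-missing")
  }
  if (any(values < 0)) stop_invalid("stream values must be non-negative")
  structure(
    list(horizon_years = length(values), values = as.numeric(values),
         basis = basis, scheme_label = scheme_label),
    class = "cashflow_stream"
  )
}

#' @export
print.cashflow_stream <- function(x, ...) {
  cat(sprintf("Cashflow stream '%s' (%s), %d years, total %s, max yearly %s\n",
              x$scheme_label, x$basis, x$horizon_years,
              fmt_eur(sum(x$values)), fmt_eur(max(x$values))))
  invisible(x)
}

#' @export
as.data.frame.cashflow_stream <- function(x, ...) {
  data.frame(
    year = seq_len(x$horizon_years) - 1L,
    scheme_label = x$scheme_label,
    basis = x$basis,
    value = x$values
  )
}

#' @export
plot.cashflow_stream <- function(x, ...,
                                 xlab = "model year",
                                 ylab = sprintf("budget impact (%s)", x$basis),
                                 type = "h") {
  graphics::plot(seq_len(x$horizon_years) - 1L, x$values,
                 type = type, xlab = xlab, ylab = ylab,
                 main = x$scheme_label, ...)
  invisible(x)
}

#' Budget-impact stream under upfront lump-sum payment
#'
#' Every patient is paid for in full in the year therapy starts:
#' `value_t = price * initiated_t`.
#'
#' @param flow A [patient_flow()] result.
#' @param price Upfront price per patient, positive.
#' @return A nominal [cashflow_stream] over the flow's horizon.
#' @export
build_upfront_stream <- function(flow, price) {
  check_number(price, "price", lower = 0, strict_lower = TRUE)
  cashflow_stream(price * flow$initiated, basis = "nominal",
                  scheme_label = "upfront")
}

#' Budget-impact stream under annuity-based payment
#'
#' Per-patient ledger semantics: every patient starting therapy in year `s`
#' owes the annuity `A` at the beginning of years `s, s+1, ..., s+n-1`, so the
#' payer's bill in year `t` is `A` times the number of patients initiated in
#' years `t-(n-1) .. t`. Under the `window_only` policy, payments falling in
#' years at or beyond the horizon are dropped (they remain owed in the
#' manufacturer's contract view); under `full_ledger` the stream is extended
#' to year `T + n - 2` so the ledger is complete.
#'
#' @param flow A [patient_flow()] result.
#' @param scheme A [payment_scheme()] with `modality = "annuity"`.
#' @param policy A [truncation_policy()] (or its mode string); default
#'   `"window_only"`.
#' @return A nominal [cashflow_stream]; its `horizon_years` equals the flow
#'   horizon under `window_only` and `T + n - 1` under `full_ledger`.
#' @examples
#' sp <- epi_spec(prevalence_rate = 0, incidence_rate = 2e-6)
#' fl <- patient_flow(sp, 10)
#' build_abp_stream(fl, payment_scheme(1e6, n_payments = 5, bond_rate = 0.03))
#' @export
build_abp_stream <- function(flow, scheme, policy = truncation_policy()) {
  policy <- as_truncation(policy)
  if (!inherits(scheme, "payment_scheme") || scheme$modality != "annuity") {
    stop_invalid("'scheme' must be a payment_scheme with modality 'annuity'")
  }
  n <- scheme$n_payments
  T_ <- flow$horizon_years
  if (policy$mode == "window_only" && n > T_) {
    warning(sprintf(
      "annuity count n = %d exceeds the %d-year horizon; payments beyond the window are dropped",
      n, T_), call. = FALSE)
  }
  a <- annuity_due(scheme$price, scheme$bond_rate, n)$annuity_amount
  out_len <- if (policy$mode == "full_ledger") T_ + n - 1L else T_
  values <- numeric(out_len)
  # year t collects one annuity from every cohort initiated in t-(n-1) .. t
  for (s in seq_len(T_) - 1L) {
    yrs <- s + 0:(n - 1L)
    yrs <- yrs[yrs < out_len]
    values[yrs + 1L] <- values[yrs + 1L] + a * flow$initiated[s + 1L]
  }
  cashflow_stream(values, basis = "nominal", scheme_label = scheme$label)
}
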