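#' Annuity-due repayment schedule for a negotiated upfront price
#'
#' Converts a one-time therapy price (the principal `P`) into `n` equal yearly
#' annuities due at the *beginning* of each payment year, priced at a bond
#' rate `i`. The annuity amount is
#' \deqn{A = \frac{iP}{1 - (1+i)^{-n}} \cdot \frac{1}{1+i}, \qquad i > 0,}
#' with the analytic zero-rate limit \eqn{A = P/n}. By construction the net
#' present value of the schedule at the bond rate equals the principal: the
#' manufacturer financing the spread payments on the bond market is exactly
#' compensated for its opportunity cost of capital.
#'
#' @param principal Upfront price `P` in currency units; must be positive.
#' @param bond_rate Yearly bond (financing) rate `i` as a fraction, e.g.
#'   `0.03` for a 3\% health impact bond; must be non-negative.
#' @param n_payments Number of yearly annuities `n`; integer, at least 1.
#'
#' @return An object of class `annuity_schedule`: a list with elements
#'   `annuity_amount`, `n_payments`, `bond_rate`, `principal` and
#'   `payment_offsets` (years `0, 1, ..., n-1` after treatment, payments due
#'   at the start of each year).
#'
#' @examples
#' # a EUR 1m therapy financed over 5 years at a 3% government bond rate
#' annuity_due(1e6, 0.03, 5)
#' # the same therapy on a 10% corporate bond costs more per year
#' annuity_due(1e6, 0.10, 5)$annuity_amount
#' # one payment is just the upfront price, whatever the rate
#' annuity_due(1e6, 0.07, 1)$annuity_amount
#' @seealso [npv()] for the schedule/principal identity.
#' @export
annuity_due <- function(principal, bond_rate, n_payments) {
  check_number(principal, "principal", lower = 0, strict_lower = TRUE)
  check_number(bond_rate, "bond_rate", lower = 0)
  check_number(n_payments, "n_payments", lower = 1, integer = TRUE)
  n <- as.integer(n_payments)
  a <- if (n == 1L) {
    principal # the algebra forces A = P for a single payment, any rate
  } else if (bond_rate > 0) {
    bond_rate * principal / (1 - (1 + bond_rate)^(-n)) / (1 + bond_rate)
  } else {
    principal / n # analytic i -> 0 limit of the annuity-due formula
  }
  structure(
    list(
      annuity_amount  = a,
      n_payments      = n,
      bond_rate       = bond_rate,
      principal       = principal,
      payment_offsets = 0:(n - 1L)
    ),
    class = "annuity_schedule"
  )
}

#' @export
print.annuity_schedule <- function(x, ...) {
  cat(sprintf(
    "Annuity-due schedule: %d yearly payment(s) of %s (principal %s, bond rate %.2f%%)\n",
    x$n_payments, fmt_eur(x$annuity_amount), fmt_eur(x$principal),
    100 * x$bond_rate
  ))
  invisible(x)
}

#' Net present value of a cashflow
#'
#' Discounts a time-indexed cashflow back to year 0 (the first model year) and
#' sums: \eqn{\mathrm{NPV} = \sum_t x_t (1+r)^{-t}} with `t = 0` for the first
#' entry, so a payment in the first year is not discounted. Methods exist for
#' bare numeric vectors, [cashflow_stream] objects and [annuity_due()]
#' schedules (where payments sit at the schedule's offsets).
#'
#' @param x A numeric vector of yearly values starting at year 0, a
#'   `cashflow_stream`, or an `annuity_schedule`.
#' @param rate Discount rate per year as a fraction; must exceed -1.
#' @param ... Passed on to methods.
#' @return A single number in the currency units of `x`.
#' @examples
#' npv(c(100, 100), 0.03)                 # 100 + 100/1.03
#' npv(annuity_due(1e6, 0.05, 10), 0.05)  # recovers the principal
#' @export
npv <- function(x, rate, ...) UseMethod("npv")

#' @rdname npv
#' @export
npv.default <- function(x, rate, ...) {
  check_number(rate, "rate", lower = -1, strict_lower = TRUE)
  if (length(x) == 0L) return(0)
  if (!is.numeric(x)) stop_invalid("'x' must be numeric")
  t <- seq_along(x) - 1
  sum(x / (1 + rate)^t)
}

#' @rdname npv
#' @export
npv.cashflow_stream <- function(x, rate, ...) {
  npv.default(x$values, rate)
}

#' @rdname npv
#' @export
npv.annuity_schedule <- function(x, rate, ...) {
  check_number(rate, "rate", lower = -1, strict_lower = TRUE)
  sum(x$annuity_amount / (1 + rate)^x$payment_offsets)
}

#' Discount a cashflow stream to present values
#'
#' Applies the elementwise discount factor \eqn{(1+r)^{-t}}, `t = 0` for the
#' first model year, and marks the result as discounted. Discounting an
#' already-discounted stream is an error so a stream can never be discounted
#' twice by accident.
#'
#' @param stream A nominal [cashflow_stream].
#' @param rate Discount rate per year as a fraction (e.g. the social discount
#'   rate, `0.03`); must exceed -1.
#' @return A `cashflow_stream` with `basis = "discounted"` and the same
#'   horizon and label.
#' @examples
#' s <- cashflow_stream(c(100, 100, 100), scheme_label = "demo")
#' discount_stream(s, 0.03)
#' @export
discount_stream <- function(stream, rate) {
  check_flag_basis(stream, "nominal", "stream")
  check_number(rate, "rate", lower = -1, strict_lower = TRUE)
  t <- seq_along(stream$values) - 1
  cashflow_stream(stream$values / (1 + rate)^t,
                  basis = "discounted",
                  scheme_label = stream$scheme_label)
}
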