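# internal validation helpers; all user-facing errors carry an abpsim condition
# class so the CLI can map them to exit codes (config error vs infeasible input)

stop_invalid <- function(msg) {
  stop(errorCondition(msg, class = c("abpsim_invalid_parameter", "abpsim_error")))
}

stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("abpsim_config_error", "abpsim_error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_invalid(sprintf("'%s' must be > %s (got %s)", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_invalid(sprintf("'%s' must be >= %s (got %s)", name, lower, x))
  }
  if (x > upper) {
    stop_invalid(sprintf("'%s' must be <= %s (got %s)", name, upper, x))
  }
  if (integer && x != trunc(x)) {
    stop_invalid(sprintf("'%s' must be a whole number (got %s)", name, x))
  }
  x
}

check_flag_basis <- function(stream, basis, what) {
  if (!inherits(stream, "cashflow_stream")) {
    stop_invalid(sprintf("'%s' must be a cashflow_stream", what))
  }
  if (stream$basis != basis) {
    stop_invalid(sprintf("'%s' must be on the %s basis (got %s)",
                         what, basis, stream$basis))
  }
  invisible(stream)
}

fmt_eur <- function(x) formatC(round(x), format = "d", big.mark = ",")
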