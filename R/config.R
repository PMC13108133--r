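# scenario configuration: YAML load/save with field-level validation.
# rates may be written either as fractions (0.03) or as "1/10700"-style
# strings so rare-disease rates can be encoded exactly as usually quoted.

config_defaults <- function() {
  list(
    name = "default",
    epidemiology = list(
      prevalence_rate = 1 / 10700,
      incidence_rate = 1 / 750000,
      incidence_basis = "births",
      population_size = 11.5e6,
      births_per_year = 120000,
      growth_rate = 0,
      backlog_spread_years = 1L,
      disease_duration_years = 70,
      uptake_fraction = 1
    ),
    economics = list(
      budget_cap = 250e6,
      social_discount_rate = 0.03,
      inflation_rate = 0,
      horizon_years = 25L
    ),
    price = 1e6,
    durability_years = 75,
    truncation = "window_only",
    schemes = list(),
    output = list()
  )
}

rate_fields <- c("prevalence_rate", "incidence_rate", "uptake_fraction",
                 "social_discount_rate", "inflation_rate", "growth_rate",
                 "bond_rate")

parse_rate <- function(value, key) {
  if (is.character(value) && length(value) == 1L &&
      grepl("^\\s*[0-9.]+\\s*/\\s*[0-9.]+\\s*$", value)) {
    parts <- as.numeric(strsplit(value, "/")[[1]])
    value <- parts[1] / parts[2]
  }
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop_config(sprintf("config field '%s' must be a number or 'a/b' string",
                        key))
  }
  if (value > 1) {
    stop_config(sprintf(
      "config field '%s' is %s: rates must be fractions (write 0.03 for 3%%)",
      key, value))
  }
  value
}

check_known_keys <- function(given, allowed, where) {
  bad <- setdiff(names(given), allowed)
  if (length(bad)) {
    stop_config(sprintf("unknown config key(s) in %s: %s", where,
                        paste(bad, collapse = ", ")))
  }
}

merge_section <- function(given, defaults, where) {
  check_known_keys(given, names(defaults), where)
  missing <- setdiff(names(defaults), names(given))
  if (length(missing) && length(given)) {
    message(sprintf("config: %s using defaults for: %s", where,
                    paste(missing, collapse = ", ")))
  }
  out <- defaults
  for (k in names(given)) {
    v <- given[[k]]
    if (k %in% rate_fields) v <- parse_rate(v, k)
    out[[k]] <- v
  }
  out
}

#' Load and validate a scenario configuration
#'
#' Reads a YAML scenario file, fills defaults for anything not given (the
#' packaged default scenario is the prevalence-dominant LCA setting), parses
#' `"1/10700"`-style rational rate strings, and validates every field.
#' Unknown keys are rejected by name; rates written as percentages
#' (values above 1) are rejected with a hint. An empty file yields the full
#' default scenario with a warning. Every section that falls back to
#' defaults is logged to standard error.
#'
#' @param path Path to a YAML config file.
#' @return An object of class `scenario_config`: a list with elements
#'   `name`, `epidemiology` ([epi_spec()]), `economics` ([econ_spec()]),
#'   `price`, `durability_years`, `truncation` ([truncation_policy()]),
#'   `schemes` (list of [payment_scheme()]) and `output` (named paths).
#' @seealso [write_config()] for the inverse; [abp_preset()] for the
#'   packaged scenarios.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_config(sprintf("config file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) {
    warning("config file is empty; using all defaults", call. = FALSE)
    raw <- list()
  }
  def <- config_defaults()
  check_known_keys(raw, names(def), "top level")

  epi_args <- merge_section(raw$epidemiology %||% list(),
                            def$epidemiology, "epidemiology")
  if (is.null(epi_args$disease_duration_years)) {
    epi_args$disease_duration_years <- NA_real_
  }
  econ_args <- merge_section(raw$economics %||% list(),
                             def$economics, "economics")

  price <- raw$price %||% def$price
  check_number(price, "price", lower = 0, strict_lower = TRUE)
  durability <- raw$durability_years %||% def$durability_years
  check_number(durability, "durability_years", lower = 0, strict_lower = TRUE)
  trunc_mode <- raw$truncation %||% def$truncation
  schemes <- lapply(raw$schemes %||% def$schemes, function(s) {
    check_known_keys(s, c("bond_type", "bond_rate", "n_payments", "label"),
                     "schemes")
    payment_scheme(price,
                   n_payments = s$n_payments %||% 1,
                   bond_rate = parse_rate(s$bond_rate %||% 0, "bond_rate"),
                   bond_type = s$bond_type %||% "health_impact",
                   label = s$label)
  })
  output <- raw$output %||% def$output
  check_known_keys(output, c("report_path", "stream_path"), "output")

  structure(
    list(
      name = raw$name %||% def$name,
      epidemiology = do.call(epi_spec, epi_args),
      economics = do.call(econ_spec, econ_args),
      price = price,
      durability_years = durability,
      truncation = as_truncation(trunc_mode),
      schemes = schemes,
      output = output
    ),
    class = "scenario_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration back to YAML
#'
#' Serialises a `scenario_config` so that [load_config()] recovers an equal
#' object (round-trip property).
#'
#' @param config A `scenario_config`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  epi <- unclass(config$epidemiology)
  if (is.na(epi$disease_duration_years)) epi$disease_duration_years <- NULL
  out <- list(
    name = config$name,
    epidemiology = epi,
    economics = unclass(config$economics),
    price = config$price,
    durability_years = config$durability_years,
    truncation = config$truncation$mode,
    schemes = lapply(config$schemes, function(s) {
      list(bond_type = s$bond_type, bond_rate = s$bond_rate,
           n_payments = s$n_payments, label = s$label)
    }),
    output = config$output
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario config '%s' (%s)\n", x$name,
              classify_dominance(x$epidemiology)))
  cat(sprintf("  price %s, durability %g y, truncation %s, %d scheme(s)\n",
              fmt_eur(x$price), x$durability_years, x$truncation$mode,
              length(x$schemes)))
  print(x$epidemiology)
  print(x$economics)
  invisible(x)
}

#' Write a report table as deterministic CSV
#'
#' Writes condition-report or feasibility-grid tables with a fixed column
#' order (as given), ratio columns (`*_ratio`) rendered to 2 decimal places
#' in the style of the published tables, and a trailing newline. Re-running
#' on the same input produces byte-identical output.
#'
#' @param table A data.frame (e.g. from [run_preset()] or
#'   [feasibility_sweep()]); an empty table writes the header only.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  if (!is.data.frame(table)) stop_invalid("'table' must be a data.frame")
  out <- table
  for (nm in names(out)) {
    if (grepl("_ratio$", nm)) {
      out[[nm]] <- sprintf("%.2f", out[[nm]])
    } else if (is.numeric(out[[nm]])) {
      out[[nm]] <- format(out[[nm]], trim = TRUE, scientific = FALSE, digits = 15)
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
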