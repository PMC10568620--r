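#' Regimen growth and mutation rates used throughout the package
#'
#' A regimen parameter table holds, for each drug regimen, the per-day net
#' growth rates of the four genotypes and the five irreversible mutation
#' rates of the model:
#'
#' * `a`, `b`, `c`, `f` — net growth rates (per day) of Type-W (sensitive to
#'   both drugs), Type-X (T790M, resistant to drug A), Type-Y (C797S,
#'   resistant to drug B) and Type-Z (doubly resistant). Negative values mean
#'   net decline under the drug.
#' * `g`, `h`, `k` — mutation rates (per day) from W to X, Y and Z.
#' * `p`, `q` — mutation rates from X to Z and from Y to Z.
#'
#' `default_parameter_table()` returns the literature-derived rates for the
#' three regimens studied: regimen A (erlotinib/gefitinib), regimen B
#' (osimertinib) and regimen C (the erlotinib + osimertinib combination),
#' with every mutation rate at 1e-7 per day.
#'
#' @return A tibble with columns `regimen`, `a`, `b`, `c`, `f`, `g`, `h`,
#'   `k`, `p`, `q` and one row per regimen.
#' @examples
#' default_parameter_table()
#' @export
default_parameter_table <- function() {
  tibble(
    regimen = c("A", "B", "C"),
    a = c(-0.17, -0.32, -0.064),
    b = c(0.045, -0.15, -0.0335),
    c = c(-0.13, 0.024, -0.0335),
    f = c(0.022, 0.022, 0.022),
    g = 1e-7, h = 1e-7, k = 1e-7, p = 1e-7, q = 1e-7
  )
}

#' Names of the rate parameters of one regimen
#' @keywords internal
rate_names <- c("a", "b", "c", "f", "g", "h", "k", "p", "q")

growth_names <- c("a", "b", "c", "f")
mutation_names <- c("g", "h", "k", "p", "q")

#' Validate a regimen parameter table
#'
#' Checks that `params` has the required columns, finite growth rates and
#' non-negative mutation rates, and that every regimen in `required` is
#' present.
#'
#' @param params A parameter table as returned by
#'   [default_parameter_table()].
#' @param required Character vector of regimen labels that must be present.
#' @return `params`, invisibly, after validation.
#' @export
validate_parameter_table <- function(params, required = character()) {
  if (!is.data.frame(params)) {
    abort("`params` must be a data frame.", class = "tki_error_params")
  }
  missing_cols <- setdiff(c("regimen", rate_names), names(params))
  if (length(missing_cols) > 0) {
    abort(
      paste0("`params` is missing columns: ", paste(missing_cols, collapse = ", ")),
      class = "tki_error_params"
    )
  }
  if (anyDuplicated(params$regimen)) {
    abort("`params` has duplicated regimen labels.", class = "tki_error_params")
  }
  vals <- as.matrix(params[rate_names])
  if (!all(is.finite(vals))) {
    abort("All rates must be finite.", class = "tki_error_params")
  }
  if (any(as.matrix(params[mutation_names]) < 0)) {
    abort("Mutation rates g, h, k, p, q must be >= 0.", class = "tki_error_params")
  }
  absent <- setdiff(required, params$regimen)
  if (length(absent) > 0) {
    abort(
      paste0("Regimen(s) not defined in `params`: ", paste(absent, collapse = ", ")),
      class = "tki_error_unknown_regimen"
    )
  }
  invisible(params)
}

#' Extract one regimen's rates as a named list
#'
#' @inheritParams validate_parameter_table
#' @param regimen A single regimen label present in `params`.
#' @return Named list with elements `a`, `b`, `c`, `f`, `g`, `h`, `k`, `p`,
#'   `q` and `label`.
#' @export
regimen_rates <- function(params, regimen) {
  validate_parameter_table(params, required = regimen)
  row <- params[params$regimen == regimen, , drop = FALSE]
  out <- as.list(row[1, rate_names])
  out$label <- regimen
  out
}

#' Replace one rate of one regimen
#'
#' Convenience for sensitivity analyses: returns the table with the single
#' entry `(regimen, parameter)` set to `value`, all else untouched.
#'
#' @inheritParams regimen_rates
#' @param parameter One of `"a","b","c","f","g","h","k","p","q"`.
#' @param value Replacement rate (per day).
#' @return The modified parameter table.
#' @export
set_rate <- function(params, regimen, parameter, value) {
  validate_parameter_table(params, required = regimen)
  if (!parameter %in% rate_names) {
    abort(
      paste0("Unknown parameter name: ", parameter),
      class = "tki_error_unknown_parameter"
    )
  }
  params[params$regimen == regimen, parameter] <- value
  params
}
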