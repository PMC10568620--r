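# Seeded scenario generator: random regimen parameter tables and initial
# compositions sharing the structural assumptions the analyses rely on
# (sign structure of the drug effects, log-uniform resistant fractions),
# so every stage can be property-tested without external data.
#
# Randomness uses R's default Mersenne-Twister generator via
# withr::with_seed, so draws are reproducible across runs and platforms
# for a fixed seed and leave the caller's RNG state untouched.

#' Configuration of the synthetic scenario generator
#'
#' Defines the sampling ranges for random regimen parameter tables and
#' initial tumor compositions. Growth rates are drawn uniformly within
#' +/- `growth_spread` of the corresponding default magnitude, preserving
#' the sign structure of the drug effects (under A: W and Y decline, X and
#' Z grow; under B: W and X decline, Y and Z grow; under C: only Z grows).
#' Mutation rates are log-uniform in `mutation_rate_range`. Initial X, Y,
#' Z fractions are log-uniform in their ranges with W the remainder.
#'
#' @param seed Integer RNG seed.
#' @param growth_spread Relative half-width of the growth-rate intervals
#'   around the default magnitudes (default 0.5).
#' @param mutation_rate_range Log-uniform interval for the five mutation
#'   rates, within (0, 1e-3).
#' @param total_cells Initial total cell number (default 1e9).
#' @param x_range,y_range,z_range Log-uniform intervals of the initial
#'   resistant fractions.
#' @return A list of class `tki_scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            growth_spread = 0.5,
                            mutation_rate_range = c(1e-9, 1e-5),
                            total_cells = 1e9,
                            x_range = c(1e-8, 1e-2),
                            y_range = c(1e-8, 1e-2),
                            z_range = c(1e-9, 1e-5)) {
  ranges <- list(mutation_rate_range, x_range, y_range, z_range)
  if (any(vapply(ranges, function(r) length(r) != 2 || r[1] > r[2] || r[1] <= 0, logical(1)))) {
    abort("Ranges must be ordered pairs of positive numbers.", class = "tki_error_config")
  }
  if (mutation_rate_range[2] >= 1e-3) {
    abort("Mutation-rate range must lie within (0, 1e-3).", class = "tki_error_config")
  }
  if (growth_spread < 0 || growth_spread >= 1) {
    abort("`growth_spread` must lie in [0, 1).", class = "tki_error_config")
  }
  structure(
    list(
      seed = as.integer(seed), growth_spread = growth_spread,
      mutation_rate_range = mutation_rate_range, total_cells = total_cells,
      x_range = x_range, y_range = y_range, z_range = z_range
    ),
    class = "tki_scenario_config"
  )
}

# internal: log-uniform draw
runif_log <- function(n, range) {
  10^stats::runif(n, log10(range[1]), log10(range[2]))
}

#' Draw a random regimen parameter table
#'
#' Samples growth rates within `growth_spread` of the default magnitudes
#' (signs preserved per regimen) and log-uniform mutation rates, rejecting
#' draws whose growth rates nearly coincide (which would make the
#' closed-form cascade ill-conditioned). At most 1000 rejections are
#' attempted before an error is signalled.
#'
#' @param config A [scenario_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A regimen parameter table (see [default_parameter_table()]).
#' @export
sample_regimen_parameters <- function(config = scenario_config(), seed = NULL) {
  stopifnot(inherits(config, "tki_scenario_config"))
  withr::with_seed(seed %||% config$seed, {
    defaults <- default_parameter_table()
    for (try in seq_len(1000)) {
      tab <- defaults
      for (i in seq_len(nrow(tab))) {
        for (nm in growth_names) {
          v <- tab[[nm]][i]
          lo <- abs(v) * (1 - config$growth_spread)
          hi <- abs(v) * (1 + config$growth_spread)
          tab[[nm]][i] <- sign(v) * stats::runif(1, lo, hi)
        }
        for (nm in mutation_names) {
          tab[[nm]][i] <- runif_log(1, config$mutation_rate_range)
        }
      }
      degenerate <- any(vapply(
        tab$regimen,
        function(r) is_degenerate_rates(regimen_rates(tab, r)),
        logical(1)
      ))
      if (!degenerate) {
        return(tab)
      }
    }
    abort(
      "Rejection sampling exhausted: could not draw non-degenerate rates.",
      class = "tki_error_sampling"
    )
  })
}

#' Draw a random initial tumor composition
#'
#' X, Y and Z fractions are log-uniform in the configured ranges; Type-W
#' absorbs the remainder so the total is exactly `total_cells`.
#'
#' @inheritParams sample_regimen_parameters
#' @return A one-row state tibble (see [tumor_state()]).
#' @export
sample_initial_state <- function(config = scenario_config(), seed = NULL) {
  stopifnot(inherits(config, "tki_scenario_config"))
  withr::with_seed(seed %||% config$seed, {
    fx <- runif_log(1, config$x_range)
    fy <- runif_log(1, config$y_range)
    fz <- runif_log(1, config$z_range)
    tot <- config$total_cells
    standard_initial_state(tot, fx * tot, fy * tot, fz * tot)
  })
}

#' Draw complete scenarios (parameter table + initial state)
#'
#' @inheritParams sample_regimen_parameters
#' @param n Number of scenarios.
#' @return Tibble with columns `scenario`, `params` (list of parameter
#'   tables) and `initial` (list of states); sub-seeds are derived from
#'   `config$seed` so scenario `i` is reproducible in isolation.
#' @export
sample_scenarios <- function(config = scenario_config(), n = 1) {
  seeds <- config$seed + seq_len(n) - 1L
  tibble(
    scenario = seq_len(n),
    params = lapply(seeds, function(s) sample_regimen_parameters(config, seed = s)),
    initial = lapply(seeds, function(s) sample_initial_state(config, seed = s + 10000L))
  )
}
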