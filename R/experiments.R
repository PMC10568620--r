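# The five computational experiments: switch-time sweep, initial-proportion
# dependence, therapy-selection map, parameter sensitivity, and
# selection-map area composition. All are pure functions of (parameter
# table, initial composition, grids) and rely only on the closed-form
# propagator, so repeated runs are bit-identical.

STRATEGIES <- c("A-first", "B-first", "C")

# internal: day-`horizon` totals of the three named strategies for a state
# vector, using prefetched rate lists
strategy_finals_vector <- function(s, pars, switch_days, horizon,
                                   strategies = STRATEGIES) {
  out <- numeric(length(strategies))
  for (i in seq_along(strategies)) {
    out[i] <- switch(strategies[i],
      "A-first" = final_total_vector(
        s, pars[c("A", "B")],
        c(switch_days[["A-first"]], horizon - switch_days[["A-first"]])
      ),
      "B-first" = final_total_vector(
        s, pars[c("B", "A")],
        c(switch_days[["B-first"]], horizon - switch_days[["B-first"]])
      ),
      "C" = final_total_vector(s, pars["C"], horizon)
    )
  }
  setNames(out, strategies)
}

prefetch_rates <- function(params, regimens = c("A", "B", "C")) {
  setNames(lapply(regimens, function(r) regimen_rates(params, r)), regimens)
}

# internal: initial state vector with one resistant type set from a
# proportion of `total`, the others at their standard counts
composition_vector <- function(total, x0, y0, z0) {
  w0 <- total - x0 - y0 - z0
  if (w0 <= 0) {
    abort(
      "Invalid composition: resistant counts exhaust the total.",
      class = "tki_error_composition"
    )
  }
  c(w = w0, x = x0, y = y0, z = z0)
}

#' Day-1000 total as a function of the drug-switching day
#'
#' For a two-phase sequential strategy, sweeps the switch day over a grid
#' and records the total cell number at the horizon for each, locating the
#' optimal switching time.
#'
#' @param params Regimen parameter table.
#' @param strategy `"A-first"` (drug A then B) or `"B-first"` (B then A).
#' @param switch_days Integer switch days to test (default 1..999).
#' @param initial One-row initial state (default [standard_initial_state()]).
#' @param horizon Treatment time in days (default 1000).
#' @return Tibble of class `tki_switch_sweep` with columns `strategy`,
#'   `switch_day`, `final_total`. `glance()` reports the minimum and its
#'   argmin.
#' @examples
#' sweep <- default_parameter_table() |>
#'   sweep_switch_time("B-first", switch_days = seq(50, 950, by = 50))
#' glance(sweep)
#' @export
sweep_switch_time <- function(params, strategy = c("A-first", "B-first"),
                              switch_days = 1:999,
                              initial = standard_initial_state(),
                              horizon = 1000) {
  strategy <- match.arg(strategy)
  if (any(switch_days < 0 | switch_days > horizon)) {
    abort("`switch_days` must lie in [0, horizon].", class = "tki_error_schedule")
  }
  pars <- prefetch_rates(params, c("A", "B"))
  ordered <- if (strategy == "A-first") pars[c("A", "B")] else pars[c("B", "A")]
  s <- as_state_vector(initial)
  finals <- vapply(
    switch_days,
    function(d) final_total_vector(s, ordered, c(d, horizon - d)),
    numeric(1)
  )
  new_tki_result(
    tibble(strategy = strategy, switch_day = switch_days, final_total = finals),
    "tki_switch_sweep",
    horizon = horizon
  )
}

#' Default proportion grids for the initial-composition sweeps
#'
#' Decade endpoints 1e-8..1e-1 for Type-X and Type-Y and 1e-9..1e-5 for
#' Type-Z, optionally refined with log-spaced points between decades.
#'
#' @param varied_type `"X"`, `"Y"` or `"Z"`.
#' @param per_decade Number of log-spaced points per decade (default 8);
#'   the exact decade points are always included.
#' @return Increasing numeric vector of initial proportions.
#' @export
default_proportion_grid <- function(varied_type = c("X", "Y", "Z"),
                                    per_decade = 8) {
  varied_type <- match.arg(varied_type)
  rng <- if (varied_type == "Z") c(-9, -5) else c(-8, -1)
  fine <- 10^seq(rng[1], rng[2], by = 1 / per_decade)
  sort(unique(c(10^seq(rng[1], rng[2]), fine)))
}

#' Day-1000 total as a function of one initial resistant proportion
#'
#' Varies the initial proportion of a single resistant genotype while the
#' other two stay at their standard counts (X0 = Y0 = 1e4, Z0 = 10) and
#' the total is held at `total`, Type-W absorbing the remainder. Records
#' the horizon total for each tested strategy.
#'
#' @inheritParams sweep_switch_time
#' @param varied_type Which genotype's proportion to vary: `"X"`, `"Y"`
#'   or `"Z"`.
#' @param proportions Initial fractions in (0, 1), strictly increasing
#'   (default [default_proportion_grid()]).
#' @param strategies Strategies to evaluate (default all three).
#' @param total Initial total cell number (default 1e9).
#' @param x0,y0,z0 Standard counts of the non-varied types.
#' @param switch_days Named switch days for `"A-first"` and `"B-first"`.
#' @return Tibble of class `tki_proportion_sweep` with columns
#'   `varied_type`, `proportion`, `strategy`, `final_total`.
#' @export
sweep_initial_proportion <- function(params, varied_type = c("X", "Y", "Z"),
                                     proportions = NULL,
                                     strategies = STRATEGIES,
                                     total = 1e9, x0 = 1e4, y0 = 1e4, z0 = 10,
                                     switch_days = DEFAULT_SWITCH_DAYS,
                                     horizon = 1000) {
  varied_type <- match.arg(varied_type)
  strategies <- match.arg(strategies, STRATEGIES, several.ok = TRUE)
  proportions <- proportions %||% default_proportion_grid(varied_type)
  if (any(proportions <= 0 | proportions >= 1) ||
    any(diff(proportions) <= 0)) {
    abort(
      "`proportions` must be strictly increasing within (0, 1).",
      class = "tki_error_composition"
    )
  }
  pars <- prefetch_rates(params)
  rows <- purrr::map(proportions, function(pr) {
    cnt <- pr * total
    s <- switch(varied_type,
      X = composition_vector(total, cnt, y0, z0),
      Y = composition_vector(total, x0, cnt, z0),
      Z = composition_vector(total, x0, y0, cnt)
    )
    finals <- strategy_finals_vector(s, pars, switch_days, horizon, strategies)
    tibble(
      varied_type = varied_type, proportion = pr,
      strategy = strategies, final_total = unname(finals)
    )
  })
  new_tki_result(bind_rows(rows), "tki_proportion_sweep", horizon = horizon)
}

#' Therapy selection map over initial Type-X and Type-Y proportions
#'
#' For each cell of a grid of initial Type-X and Type-Y fractions (Type-Z
#' held constant, default 10 cells), computes the horizon totals of the
#' three strategies and labels the one achieving the smallest tumor.
#' Finals agreeing to a relative 1e-9 are treated as tied and resolved by
#' the fixed precedence B-first > A-first > C.
#'
#' @inheritParams sweep_initial_proportion
#' @param x_props,y_props Grids of initial Type-X and Type-Y fractions
#'   (default 25 log-spaced points over 1e-8..1e-1).
#' @param z0 Constant initial Type-Z count (default 10).
#' @return Tibble of class `tki_selection_map` with columns `x_prop`,
#'   `y_prop`, `final_A_first`, `final_B_first`, `final_C`, `best`, `tie`.
#' @examples
#' map <- default_parameter_table() |>
#'   build_selection_map(x_props = 10^seq(-8, -1, length.out = 5),
#'                       y_props = 10^seq(-8, -1, length.out = 5))
#' glance(map)
#' @export
build_selection_map <- function(params,
                                x_props = 10^seq(-8, -1, length.out = 25),
                                y_props = 10^seq(-8, -1, length.out = 25),
                                z0 = 10, total = 1e9,
                                switch_days = DEFAULT_SWITCH_DAYS,
                                horizon = 1000) {
  if (any(c(x_props, y_props) <= 0 | c(x_props, y_props) >= 1)) {
    abort("Grid proportions must lie in (0, 1).", class = "tki_error_composition")
  }
  pars <- prefetch_rates(params)
  grid <- tidyr::expand_grid(x_prop = x_props, y_prop = y_props)
  finals <- purrr::pmap(grid, function(x_prop, y_prop) {
    s <- composition_vector(total, x_prop * total, y_prop * total, z0)
    strategy_finals_vector(s, pars, switch_days, horizon)
  })
  fm <- do.call(rbind, finals)
  grid$final_A_first <- fm[, "A-first"]
  grid$final_B_first <- fm[, "B-first"]
  grid$final_C <- fm[, "C"]
  lab <- apply(fm, 1, function(v) best_strategy(v))
  grid$best <- vapply(lab, `[[`, character(1), "best")
  grid$tie <- vapply(lab, `[[`, logical(1), "tie")
  new_tki_result(grid, "tki_selection_map",
    z0 = z0, total = total, horizon = horizon
  )
}

# internal: argmin with relative-1e-9 ties broken by fixed precedence
# B-first > A-first > C
best_strategy <- function(finals, rtol = 1e-9) {
  stopifnot(identical(names(finals), STRATEGIES))
  lo <- min(finals)
  tied <- finals <= lo * (1 + rtol)
  precedence <- c("B-first", "A-first", "C")
  list(
    best = precedence[precedence %in% names(finals)[tied]][1],
    tie = sum(tied) > 1
  )
}

#' Default sweep values for one rate parameter
#'
#' Growth rates (`a`, `b`, `c`, `f`) sweep the regimen's default value
#' +/- 0.1 per day on a 21-point linear grid (wide enough to cross zero);
#' mutation rates (`g`, `h`, `k`, `p`, `q`) sweep 1e-9..1e-5 on a 17-point
#' log grid, bracketing biologically plausible per-day rates.
#'
#' @inheritParams set_rate
#' @param n_growth,n_mutation Grid sizes.
#' @param growth_delta Half-width of the linear growth-rate grid (per day).
#' @param mutation_range Log-grid endpoints for mutation rates.
#' @return Numeric vector of parameter values.
#' @export
default_sensitivity_values <- function(params, regimen, parameter,
                                       n_growth = 21, n_mutation = 17,
                                       growth_delta = 0.1,
                                       mutation_range = c(1e-9, 1e-5)) {
  if (parameter %in% growth_names) {
    centre <- regimen_rates(params, regimen)[[parameter]]
    seq(centre - growth_delta, centre + growth_delta, length.out = n_growth)
  } else if (parameter %in% mutation_names) {
    10^seq(log10(mutation_range[1]), log10(mutation_range[2]),
      length.out = n_mutation
    )
  } else {
    abort(
      paste0("Unknown parameter name: ", parameter),
      class = "tki_error_unknown_parameter"
    )
  }
}

#' Sensitivity of the horizon total to one rate parameter
#'
#' For the sequential strategies the focused parameter is varied jointly
#' under the first-line regimen (grid rows) and the second-line regimen
#' (grid columns), all other rates at their defaults; for combination
#' therapy it is a one-dimensional sweep under regimen C.
#'
#' @inheritParams sweep_switch_time
#' @param parameter One of `"a","b","c","f","g","h","k","p","q"`.
#' @param strategy `"A-first"`, `"B-first"` or `"C"`.
#' @param first_values,second_values Values of the parameter under the
#'   first- and second-line regimen (sequential strategies); defaults from
#'   [default_sensitivity_values()].
#' @param values Values under regimen C (combination therapy only).
#' @param switch_days Named switch days for the sequential strategies.
#' @return Tibble of class `tki_sensitivity` with columns `parameter`,
#'   `strategy`, `first_value`, `second_value` (`NA` for `"C"`),
#'   `final_total`.
#' @export
parameter_sensitivity_grid <- function(params, parameter,
                                       strategy = c("A-first", "B-first", "C"),
                                       first_values = NULL, second_values = NULL,
                                       values = NULL,
                                       initial = standard_initial_state(),
                                       switch_days = DEFAULT_SWITCH_DAYS,
                                       horizon = 1000) {
  strategy <- match.arg(strategy)
  if (!parameter %in% rate_names) {
    abort(
      paste0("Unknown parameter name: ", parameter),
      class = "tki_error_unknown_parameter"
    )
  }
  s <- as_state_vector(initial)
  if (strategy == "C") {
    values <- values %||% default_sensitivity_values(params, "C", parameter)
    finals <- vapply(values, function(v) {
      p2 <- set_rate(params, "C", parameter, v)
      final_total_vector(s, list(regimen_rates(p2, "C")), horizon)
    }, numeric(1))
    out <- tibble(
      parameter = parameter, strategy = strategy,
      first_value = values, second_value = NA_real_, final_total = finals
    )
    return(new_tki_result(out, "tki_sensitivity", horizon = horizon))
  }
  first <- if (strategy == "A-first") "A" else "B"
  second <- if (strategy == "A-first") "B" else "A"
  first_values <- first_values %||%
    default_sensitivity_values(params, first, parameter)
  second_values <- second_values %||%
    default_sensitivity_values(params, second, parameter)
  switch_day <- switch_days[[strategy]]
  grid <- tidyr::expand_grid(
    first_value = first_values, second_value = second_values
  )
  finals <- purrr::pmap_dbl(grid, function(first_value, second_value) {
    p2 <- set_rate(params, first, parameter, first_value)
    p2 <- set_rate(p2, second, parameter, second_value)
    final_total_vector(
      s, list(regimen_rates(p2, first), regimen_rates(p2, second)),
      c(switch_day, horizon - switch_day)
    )
  })
  out <- tibble(
    parameter = parameter, strategy = strategy,
    first_value = grid$first_value, second_value = grid$second_value,
    final_total = finals
  )
  new_tki_result(out, "tki_sensitivity", horizon = horizon)
}

#' Strategy area composition of the selection map versus one parameter
#'
#' Rebuilds the therapy selection map for each value of a focused rate
#' parameter under one regimen and reports the fraction of grid cells on
#' which each strategy is optimal.
#'
#' @inheritParams parameter_sensitivity_grid
#' @param regimen Regimen under which the focused parameter is varied.
#' @param parameter_values Values to test; defaults from
#'   [default_sensitivity_values()].
#' @param n_grid Selection-map resolution per axis (default 15).
#' @param x_range,y_range Map axis ranges (initial fractions).
#' @param z0 Constant initial Type-Z count.
#' @return Tibble of class `tki_area_composition` with columns
#'   `parameter`, `regimen`, `value`, `strategy`, `fraction`; the three
#'   fractions sum to 1 for each value.
#' @export
selection_area_composition <- function(params, parameter, regimen,
                                       parameter_values = NULL,
                                       n_grid = 15,
                                       x_range = c(1e-8, 1e-1),
                                       y_range = c(1e-8, 1e-1),
                                       z0 = 10, total = 1e9,
                                       switch_days = DEFAULT_SWITCH_DAYS,
                                       horizon = 1000) {
  if (!parameter %in% rate_names) {
    abort(
      paste0("Unknown parameter name: ", parameter),
      class = "tki_error_unknown_parameter"
    )
  }
  parameter_values <- parameter_values %||%
    default_sensitivity_values(params, regimen, parameter)
  x_props <- 10^seq(log10(x_range[1]), log10(x_range[2]), length.out = n_grid)
  y_props <- 10^seq(log10(y_range[1]), log10(y_range[2]), length.out = n_grid)
  rows <- purrr::map(parameter_values, function(v) {
    p2 <- set_rate(params, regimen, parameter, v)
    map <- build_selection_map(p2,
      x_props = x_props, y_props = y_props,
      z0 = z0, total = total, switch_days = switch_days, horizon = horizon
    )
    frac <- table(factor(map$best, levels = STRATEGIES)) / nrow(map)
    tibble(
      parameter = parameter, regimen = regimen, value = v,
      strategy = STRATEGIES, fraction = as.numeric(frac)
    )
  })
  new_tki_result(bind_rows(rows), "tki_area_composition",
    n_grid = n_grid, horizon = horizon
  )
}
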