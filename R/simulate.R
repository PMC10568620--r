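#' Simulate a treatment schedule
#'
#' Propagates an initial tumor state through a piecewise-constant drug
#' schedule. Within each phase every output point is obtained by a single
#' closed-form evaluation from the phase-start state, so there is no
#' step-to-step error accumulation and the result is independent of
#' `output_step`; the exact phase-end state seeds the next phase. The
#' output grid is `{0, output_step, 2*output_step, ...}` up to the horizon
#' plus every phase boundary.
#'
#' @param params Regimen parameter table (see [default_parameter_table()]).
#' @param schedule Schedule tibble (see [treatment_schedule()]).
#' @param initial One-row initial state at time 0 (see [tumor_state()]).
#' @param output_step Output grid spacing in days (> 0, default 1).
#' @return A trajectory: tibble of class `tki_trajectory` with columns
#'   `time`, `regimen`, `w`, `x`, `y`, `z`, `total`.
#' @examples
#' default_parameter_table() |>
#'   simulate_schedule(strategy_schedule("A-first"))
#' @export
simulate_schedule <- function(params, schedule, initial = standard_initial_state(),
                              output_step = 1) {
  schedule <- treatment_schedule(schedule)
  validate_parameter_table(params, required = unique(schedule$regimen))
  if (output_step <= 0) {
    abort("`output_step` must be > 0.", class = "tki_error_schedule")
  }
  horizon <- attr(schedule, "horizon")
  grid <- sort(unique(c(
    seq(0, horizon, by = output_step), horizon,
    schedule$start, schedule$end
  )))

  pars <- lapply(schedule$regimen, function(r) regimen_rates(params, r))
  s <- as_state_vector(initial)
  rows <- vector("list", nrow(schedule) + 1L)
  rows[[1]] <- tibble(
    time = 0, regimen = schedule$regimen[1],
    w = s[["w"]], x = s[["x"]], y = s[["y"]], z = s[["z"]]
  )
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start[i]
    t1 <- schedule$end[i]
    times <- grid[grid > t0 & grid <= t1]
    if (length(times) > 0) {
      states <- vapply(
        times - t0,
        function(dt) advance_vector(s, pars[[i]], dt),
        numeric(4)
      )
      rows[[i + 1L]] <- tibble(
        time = times, regimen = schedule$regimen[i],
        w = states[1, ], x = states[2, ], y = states[3, ], z = states[4, ]
      )
    }
    s <- advance_vector(s, pars[[i]], t1 - t0)
  }
  traj <- bind_rows(rows)
  traj$total <- state_total(traj)
  new_tki_result(traj, "tki_trajectory",
    schedule = schedule, initial = as_tibble(initial)
  )
}

#' Total cell number at the end of a schedule
#'
#' Convenience wrapper returning the horizon total of
#' [simulate_schedule()], computed by exact phase-wise propagation (no
#' intermediate output grid).
#'
#' @inheritParams simulate_schedule
#' @return Total cell number at the horizon (a single number).
#' @export
final_total <- function(params, schedule, initial = standard_initial_state()) {
  schedule <- treatment_schedule(schedule)
  validate_parameter_table(params, required = unique(schedule$regimen))
  pars <- lapply(schedule$regimen, function(r) regimen_rates(params, r))
  final_total_vector(as_state_vector(initial), pars, schedule$end - schedule$start)
}

# internal fast path: state vector + list of rate lists + phase durations
final_total_vector <- function(s, pars, durations) {
  for (i in seq_along(pars)) {
    s <- advance_vector(s, pars[[i]], durations[i])
  }
  sum(s)
}

#' Tumor recurrence time of a trajectory
#'
#' The recurrence day is defined as the first time after treatment start
#' at which the total cell number climbs back to its initial value, having
#' previously dropped strictly below it (regrowth to baseline burden after
#' a treatment-induced nadir). The crossing is located by linear
#' interpolation between output grid points. Returns `NA` when the total
#' never falls below baseline, or falls but never recovers within the
#' horizon.
#'
#' @param trajectory A trajectory tibble (columns `time` and `total`), as
#'   returned by [simulate_schedule()].
#' @return The recurrence day, or `NA_real_`.
#' @export
recurrence_time <- function(trajectory) {
  stopifnot(is.data.frame(trajectory), nrow(trajectory) >= 1)
  tt <- trajectory$time
  tot <- trajectory$total
  baseline <- tot[1]
  below <- which(tot < baseline)
  if (length(below) == 0) {
    return(NA_real_)
  }
  first_below <- below[1]
  recovered <- which(tot >= baseline & seq_along(tot) > first_below)
  if (length(recovered) == 0) {
    return(NA_real_)
  }
  j <- recovered[1]
  if (tot[j] == baseline) {
    return(tt[j])
  }
  # linear interpolation on the segment crossing the baseline
  i <- j - 1L
  tt[i] + (baseline - tot[i]) / (tot[j] - tot[i]) * (tt[j] - tt[i])
}

# internal: classed-tibble constructor shared by all result types
new_tki_result <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
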