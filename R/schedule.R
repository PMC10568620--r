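#' Treatment schedules
#'
#' A treatment schedule is a tibble of contiguous phases with columns
#' `regimen`, `start`, `end`: the first phase starts at day 0, each phase
#' starts where the previous one ends, and the last phase ends at the
#' horizon. `treatment_schedule()` validates an explicit phase table;
#' `sequential_schedule()` builds the two-phase switch schedules studied
#' here, and `monotherapy_schedule()` a single-drug schedule.
#'
#' @param phases Data frame with columns `regimen`, `start`, `end`.
#' @return A validated schedule tibble with attribute `horizon`.
#' @examples
#' sequential_schedule("A", "B", switch_day = 307)
#' monotherapy_schedule("C")
#' @export
treatment_schedule <- function(phases) {
  if (!is.data.frame(phases) ||
    !all(c("regimen", "start", "end") %in% names(phases)) ||
    nrow(phases) == 0) {
    abort(
      "`phases` must be a non-empty data frame with columns regimen, start, end.",
      class = "tki_error_schedule"
    )
  }
  phases <- as_tibble(phases[c("regimen", "start", "end")])
  if (phases$start[1] != 0 ||
    any(phases$end < phases$start) ||
    (nrow(phases) > 1 &&
      any(phases$start[-1] != phases$end[-nrow(phases)]))) {
    abort(
      "Invalid schedule: phases must be contiguous, start at day 0 and have end >= start.",
      class = "tki_error_schedule"
    )
  }
  attr(phases, "horizon") <- phases$end[nrow(phases)]
  phases
}

#' @rdname treatment_schedule
#' @param first,second Regimen labels of the first- and second-line drug.
#' @param switch_day Day of the drug switch, in `[0, horizon]`.
#' @param horizon Total treatment time in days (default 1000).
#' @export
sequential_schedule <- function(first, second, switch_day, horizon = 1000) {
  if (switch_day < 0 || switch_day > horizon) {
    abort("`switch_day` must lie in [0, horizon].", class = "tki_error_schedule")
  }
  treatment_schedule(tibble(
    regimen = c(first, second),
    start = c(0, switch_day),
    end = c(switch_day, horizon)
  ))
}

#' @rdname treatment_schedule
#' @param regimen Regimen label for single-drug (or combination) therapy.
#' @export
monotherapy_schedule <- function(regimen, horizon = 1000) {
  treatment_schedule(tibble(regimen = regimen, start = 0, end = horizon))
}

# Named strategies used across the experiments. "A-first" switches from
# regimen A to B at sta (default day 307, the erlotinib mPFS), "B-first"
# from B to A at stb (default day 567, the osimertinib mPFS), and "C" is
# single-phase combination therapy.
DEFAULT_SWITCH_DAYS <- c("A-first" = 307, "B-first" = 567)

#' Build the schedule of a named treatment strategy
#'
#' @param strategy `"A-first"`, `"B-first"` or `"C"`.
#' @param switch_day Switch day for the two sequential strategies; defaults
#'   to 307 (A-first) or 567 (B-first), the median progression-free
#'   survival times that motivate the standard schedules. Ignored for
#'   `"C"`.
#' @param horizon Total treatment time in days.
#' @return A schedule tibble (see [treatment_schedule()]).
#' @export
strategy_schedule <- function(strategy = c("A-first", "B-first", "C"),
                              switch_day = NULL, horizon = 1000) {
  strategy <- match.arg(strategy)
  if (strategy == "C") {
    return(monotherapy_schedule("C", horizon = horizon))
  }
  switch_day <- switch_day %||% unname(DEFAULT_SWITCH_DAYS[strategy])
  if (strategy == "A-first") {
    sequential_schedule("A", "B", switch_day, horizon)
  } else {
    sequential_schedule("B", "A", switch_day, horizon)
  }
}
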