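# broom-style tidiers for the result classes

#' Tidy a trajectory into long format
#'
#' @param x A `tki_trajectory` from [simulate_schedule()].
#' @param ... Unused.
#' @return Tibble with columns `time`, `regimen`, `cell_type` (one of
#'   `w`, `x`, `y`, `z`, `total`) and `count`.
#' @export
tidy.tki_trajectory <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("w", "x", "y", "z", "total"),
      names_to = "cell_type", values_to = "count"
    )
}

#' One-row summary of a trajectory
#'
#' @inheritParams tidy.tki_trajectory
#' @return Tibble with `horizon`, `final_total`, `recurrence_day` and
#'   `final_dominant` (the genotype with the largest final count).
#' @export
glance.tki_trajectory <- function(x, ...) {
  last <- x[nrow(x), ]
  types <- c("w", "x", "y", "z")
  tibble(
    horizon = last$time,
    final_total = last$total,
    recurrence_day = recurrence_time(x),
    final_dominant = types[which.max(as.numeric(last[types]))]
  )
}

#' Per-strategy optimum of a switch-time sweep
#'
#' @param x A `tki_switch_sweep` from [sweep_switch_time()].
#' @param ... Unused.
#' @return Tibble with one row per strategy: `best_switch_day`,
#'   `min_final`.
#' @export
glance.tki_switch_sweep <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$strategy) |>
    slice_min(.data$final_total, n = 1, with_ties = FALSE) |>
    ungroup() |>
    rename(best_switch_day = "switch_day", min_final = "final_total")
}

#' Tidy a selection map into long format
#'
#' @param x A `tki_selection_map` from [build_selection_map()].
#' @param ... Unused.
#' @return Tibble with columns `x_prop`, `y_prop`, `strategy`,
#'   `final_total`, `best`.
#' @export
tidy.tki_selection_map <- function(x, ...) {
  as_tibble(x) |>
    tidyr::pivot_longer(
      cols = c("final_A_first", "final_B_first", "final_C"),
      names_to = "strategy", values_to = "final_total"
    ) |>
    mutate(strategy = c(
      final_A_first = "A-first", final_B_first = "B-first", final_C = "C"
    )[.data$strategy])
}

#' Area fractions of a selection map
#'
#' @inheritParams tidy.tki_selection_map
#' @return One-row tibble with the fraction of grid cells on which each
#'   strategy is optimal and the number of cells.
#' @export
glance.tki_selection_map <- function(x, ...) {
  frac <- table(factor(x$best, levels = STRATEGIES)) / nrow(x)
  tibble(
    frac_A_first = as.numeric(frac["A-first"]),
    frac_B_first = as.numeric(frac["B-first"]),
    frac_C = as.numeric(frac["C"]),
    n_cells = nrow(x)
  )
}

#' Rise thresholds of an initial-proportion sweep
#'
#' For each (varied type, strategy) series, reports the plateau final (the
#' final total at the smallest tested proportion), the overall relative
#' spread, and the smallest proportion at which the final exceeds the
#' plateau by at least `rise` (relative), or `NA` if the series never
#' rises that much.
#'
#' @param sweep A `tki_proportion_sweep` from
#'   [sweep_initial_proportion()].
#' @param rise Relative increase defining a detected rise (default 0.1).
#' @return Tibble with columns `varied_type`, `strategy`, `plateau`,
#'   `max_relative_rise`, `rise_threshold`.
#' @export
rise_thresholds <- function(sweep, rise = 0.1) {
  as_tibble(sweep) |>
    group_by(.data$varied_type, .data$strategy) |>
    arrange(.data$proportion, .by_group = TRUE) |>
    summarise(
      plateau = .data$final_total[1],
      max_relative_rise = max(.data$final_total) / .data$final_total[1] - 1,
      rise_threshold = {
        up <- .data$final_total >= .data$final_total[1] * (1 + rise)
        if (any(up)) min(.data$proportion[up]) else NA_real_
      },
      .groups = "drop"
    )
}

#' @rdname rise_thresholds
#' @param x A `tki_proportion_sweep`.
#' @param ... Unused.
#' @export
glance.tki_proportion_sweep <- function(x, ...) {
  rise_thresholds(x)
}
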