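# ggplot2 visualisations, one autoplot method per result class

strategy_colors <- c("A-first" = "#d95f02", "B-first" = "#1b9e77", "C" = "#7570b3")

#' Plot a simulated trajectory
#'
#' Cell counts of the four genotypes and the total over time, log scale,
#' with drug-switch days marked.
#'
#' @param object A `tki_trajectory` from [simulate_schedule()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tki_trajectory <- function(object, ...) {
  long <- tidy(object)
  switches <- attr(object, "schedule")$start[-1]
  p <- ggplot(long, aes(x = .data$time, y = pmax(.data$count, 1e-2),
    color = .data$cell_type, linetype = .data$cell_type)) +
    geom_line(linewidth = 0.7) +
    scale_y_log10() +
    scale_linetype_manual(values = c(
      w = "solid", x = "solid", y = "solid", z = "solid", total = "dashed"
    )) +
    labs(
      x = "time (days)", y = "cell number",
      color = "population", linetype = "population"
    ) +
    theme_minimal()
  if (length(switches) > 0) {
    p <- p + geom_vline(xintercept = switches, linetype = "dotted")
  }
  p
}

#' Plot a switch-time sweep
#'
#' @param object A `tki_switch_sweep` from [sweep_switch_time()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tki_switch_sweep <- function(object, ...) {
  ggplot(as_tibble(object), aes(
    x = .data$switch_day, y = .data$final_total, color = .data$strategy
  )) +
    geom_line(linewidth = 0.7) +
    scale_y_log10() +
    scale_color_manual(values = strategy_colors) +
    labs(x = "drug-switch day", y = "total cell number at horizon") +
    theme_minimal()
}

#' Plot an initial-proportion sweep
#'
#' @param object A `tki_proportion_sweep` from
#'   [sweep_initial_proportion()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tki_proportion_sweep <- function(object, ...) {
  ggplot(as_tibble(object), aes(
    x = .data$proportion, y = .data$final_total, color = .data$strategy
  )) +
    geom_line(linewidth = 0.7) +
    scale_x_log10() +
    scale_y_log10() +
    scale_color_manual(values = strategy_colors) +
    facet_wrap(~varied_type, scales = "free_x") +
    labs(x = "initial proportion", y = "total cell number at horizon") +
    theme_minimal()
}

#' Plot a therapy selection map
#'
#' @param object A `tki_selection_map` from [build_selection_map()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tki_selection_map <- function(object, ...) {
  ggplot(as_tibble(object), aes(
    x = .data$x_prop, y = .data$y_prop, fill = .data$best
  )) +
    geom_tile() +
    scale_x_log10() +
    scale_y_log10() +
    scale_fill_manual(values = strategy_colors) +
    labs(
      x = "initial Type-X proportion", y = "initial Type-Y proportion",
      fill = "best strategy"
    ) +
    theme_minimal()
}

#' Plot a parameter-sensitivity grid
#'
#' Two-dimensional raster (first-line value x second-line value, fill =
#' log10 final total) for the sequential strategies; a line for
#' combination therapy.
#'
#' @param object A `tki_sensitivity` from [parameter_sensitivity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tki_sensitivity <- function(object, ...) {
  df <- as_tibble(object)
  if (all(is.na(df$second_value))) {
    return(
      ggplot(df, aes(x = .data$first_value, y = .data$final_total)) +
        geom_line(linewidth = 0.7) +
        scale_y_log10() +
        facet_wrap(~parameter + strategy) +
        labs(x = "parameter value", y = "total cell number at horizon") +
        theme_minimal()
    )
  }
  ggplot(df, aes(
    x = .data$first_value, y = .data$second_value,
    fill = log10(.data$final_total)
  )) +
    geom_tile() +
    facet_wrap(~parameter + strategy, scales = "free") +
    labs(
      x = "value under first-line regimen",
      y = "value under second-line regimen",
      fill = "log10 final total"
    ) +
    theme_minimal()
}

#' Plot selection-map area composition versus a parameter
#'
#' @param object A `tki_area_composition` from
#'   [selection_area_composition()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tki_area_composition <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(
    x = .data$value, y = .data$fraction, color = .data$strategy
  )) +
    geom_line(linewidth = 0.7) +
    geom_point(size = 1) +
    scale_color_manual(values = strategy_colors) +
    facet_wrap(~parameter + regimen, scales = "free_x") +
    labs(x = "parameter value", y = "fraction of map area") +
    theme_minimal()
  if (all(df$parameter %in% mutation_names)) p <- p + scale_x_log10()
  p
}

#' @export
plot.tki_trajectory <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.tki_switch_sweep <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.tki_proportion_sweep <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.tki_selection_map <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.tki_sensitivity <- function(x, ...) print(autoplot(x, ...))
#' @export
plot.tki_area_composition <- function(x, ...) print(autoplot(x, ...))
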