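# Run configuration: a nested list mirroring the default parameter table,
# the standard initial composition, the schedule constants (sta = 307,
# stb = 567, T = 1000) and the experiment grids. Serialisable to YAML or
# JSON; omitted fields are filled from the defaults.

#' Default run configuration
#'
#' @return Nested list with entries `parameters` (per-regimen rates),
#'   `initial` (`total`, `x0`, `y0`, `z0`), `schedule` (`sta`, `stb`,
#'   `horizon`), `grids` (experiment grid settings) and `seed`.
#' @export
default_run_config <- function() {
  tab <- default_parameter_table()
  params <- lapply(seq_len(nrow(tab)), function(i) as.list(tab[i, rate_names]))
  names(params) <- tab$regimen
  list(
    parameters = params,
    initial = list(total = 1e9, x0 = 1e4, y0 = 1e4, z0 = 10),
    schedule = list(sta = 307, stb = 567, horizon = 1000),
    grids = list(
      switch_days = list(from = 1, to = 999, by = 1),
      per_decade = 8,
      map_n = 25,
      area_n = 15,
      area_values = 9,
      sensitivity = list(
        n_growth = 21, n_mutation = 17, growth_delta = 0.1,
        mutation_range = c(1e-9, 1e-5)
      ),
      flat_threshold = 0.01
    ),
    seed = 1L
  )
}

# internal: recursive default fill (x overrides defaults)
merge_config <- function(defaults, x) {
  if (!is.list(x)) {
    return(x)
  }
  for (nm in names(x)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(x[[nm]])) {
      merge_config(defaults[[nm]], x[[nm]])
    } else {
      x[[nm]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON, by file extension) configuration whose schema
#' mirrors [default_run_config()]; omitted fields are filled from the
#' defaults, so an empty file yields the full default configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "tki_error_config")
  }
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  user <- user %||% list()
  if (!is.list(user)) {
    abort("Config file must contain a mapping.", class = "tki_error_config")
  }
  validate_run_config(merge_config(default_run_config(), user))
}

#' Validate a run configuration
#'
#' @param config Configuration list (see [default_run_config()]).
#' @return `config`, after validation.
#' @export
validate_run_config <- function(config) {
  fail <- function(field, msg) {
    abort(paste0("Config field `", field, "`: ", msg), class = "tki_error_config")
  }
  for (reg in c("A", "B", "C")) {
    if (is.null(config$parameters[[reg]])) {
      fail(paste0("parameters.", reg), "regimen not defined")
    }
    unknown <- setdiff(names(config$parameters[[reg]]), rate_names)
    if (length(unknown) > 0) {
      fail(paste0("parameters.", reg, ".", unknown[1]), "unknown rate name")
    }
  }
  tab <- config_parameter_table(config)
  validate_parameter_table(tab, required = c("A", "B", "C"))
  ini <- config$initial
  if (ini$total <= ini$x0 + ini$y0 + ini$z0) {
    fail("initial.total", "must exceed x0 + y0 + z0")
  }
  sch <- config$schedule
  if (sch$horizon <= 0) fail("schedule.horizon", "must be > 0")
  for (st in c("sta", "stb")) {
    if (sch[[st]] < 0 || sch[[st]] > sch$horizon) {
      fail(paste0("schedule.", st), "must lie in [0, horizon]")
    }
  }
  config
}

#' Parameter table of a run configuration
#'
#' @inheritParams validate_run_config
#' @return Regimen parameter table (see [default_parameter_table()]).
#' @export
config_parameter_table <- function(config) {
  base <- default_parameter_table()
  for (reg in names(config$parameters)) {
    for (nm in intersect(names(config$parameters[[reg]]), rate_names)) {
      base[base$regimen == reg, nm] <- config$parameters[[reg]][[nm]]
    }
  }
  base
}

#' Write a run configuration to YAML
#'
#' @inheritParams validate_run_config
#' @param path Destination `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the three reference simulations (A-first, B-first,
#' combination) and the five experiments — switch-time sweeps,
#' initial-proportion sweeps, selection map, parameter sensitivity and
#' selection-map area composition — and writes each result as CSV plus a
#' JSON summary with the headline day-`horizon` totals, both sweep
#' minima, the recurrence days and the count of degeneracy fallbacks.
#'
#' @inheritParams validate_run_config
#' @param out_dir Output directory (created if missing).
#' @param plots Also write PNG figures for each result (default `FALSE`).
#' @param quiet Suppress progress messages.
#' @return Tibble manifest of written files (columns `stage`, `file`),
#'   invisibly.
#' @export
run_all <- function(config = default_run_config(), out_dir, plots = FALSE,
                    quiet = FALSE) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) inform(paste0(...))
  fallbacks <- 0L
  manifest <- list()
  timings <- list()
  emit <- function(stage, name, obj) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(as_tibble(obj), path)
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage, file = path)
    if (plots && inherits(obj, c(
      "tki_trajectory", "tki_switch_sweep", "tki_proportion_sweep",
      "tki_selection_map", "tki_sensitivity", "tki_area_composition"
    ))) {
      fig <- file.path(out_dir, paste0(name, ".png"))
      grDevices::png(fig, width = 1600, height = 1200, res = 200)
      print(autoplot(obj))
      grDevices::dev.off()
      manifest[[length(manifest) + 1L]] <<- tibble(stage = stage, file = fig)
    }
  }
  timed <- function(stage, expr) {
    t0 <- Sys.time()
    res <- withCallingHandlers(
      expr,
      tki_degenerate_fallback = function(c) {
        fallbacks <<- fallbacks + 1L
        invokeRestart("muffleMessage")
      }
    )
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say(sprintf("%s done in %.1fs", stage, timings[[stage]]))
    res
  }

  tab <- config_parameter_table(config)
  ini <- config$initial
  initial <- standard_initial_state(ini$total, ini$x0, ini$y0, ini$z0)
  sch <- config$schedule
  switch_days <- c("A-first" = sch$sta, "B-first" = sch$stb)
  g <- config$grids

  say("Simulating reference schedules (horizon ", sch$horizon, " days)")
  trajs <- timed("simulate", {
    lapply(c("A-first", "B-first", "C"), function(st) {
      simulate_schedule(
        tab,
        strategy_schedule(st, switch_day = switch_days[st], horizon = sch$horizon),
        initial = initial
      )
    })
  })
  names(trajs) <- c("A-first", "B-first", "C")
  for (st in names(trajs)) {
    emit("simulate", paste0("trajectory_", gsub("-", "_", st)), trajs[[st]])
  }

  sweep_days <- seq(g$switch_days$from, g$switch_days$to, by = g$switch_days$by)
  say("Switch-time sweep over ", length(sweep_days), " days per strategy")
  sweeps <- timed("sweep_switch", {
    bind_rows(
      sweep_switch_time(tab, "A-first", sweep_days, initial, sch$horizon),
      sweep_switch_time(tab, "B-first", sweep_days, initial, sch$horizon)
    )
  })
  emit("sweep_switch", "switch_sweep", sweeps)

  say("Initial-proportion sweeps (", g$per_decade, " points per decade)")
  props <- timed("sweep_proportion", {
    bind_rows(lapply(c("X", "Y", "Z"), function(ty) {
      sweep_initial_proportion(
        tab, ty,
        proportions = default_proportion_grid(ty, per_decade = g$per_decade),
        total = ini$total, x0 = ini$x0, y0 = ini$y0, z0 = ini$z0,
        switch_days = switch_days, horizon = sch$horizon
      )
    }))
  })
  emit("sweep_proportion", "proportion_sweep", props)

  say("Selection map on a ", g$map_n, "x", g$map_n, " grid")
  map <- timed("selection_map", {
    build_selection_map(
      tab,
      x_props = 10^seq(-8, -1, length.out = g$map_n),
      y_props = 10^seq(-8, -1, length.out = g$map_n),
      z0 = ini$z0, total = ini$total,
      switch_days = switch_days, horizon = sch$horizon
    )
  })
  emit("selection_map", "selection_map", map)

  say("Parameter sensitivity grids for all nine rates")
  sens_vals <- function(reg, pm) {
    default_sensitivity_values(
      tab, reg, pm,
      n_growth = g$sensitivity$n_growth, n_mutation = g$sensitivity$n_mutation,
      growth_delta = g$sensitivity$growth_delta,
      mutation_range = g$sensitivity$mutation_range
    )
  }
  sens <- timed("sensitivity", {
    bind_rows(lapply(rate_names, function(pm) {
      bind_rows(lapply(c("A-first", "B-first", "C"), function(st) {
        if (st == "C") {
          parameter_sensitivity_grid(
            tab, pm, st,
            values = sens_vals("C", pm),
            initial = initial, switch_days = switch_days, horizon = sch$horizon
          )
        } else {
          first <- if (st == "A-first") "A" else "B"
          second <- if (st == "A-first") "B" else "A"
          parameter_sensitivity_grid(
            tab, pm, st,
            first_values = sens_vals(first, pm),
            second_values = sens_vals(second, pm),
            initial = initial, switch_days = switch_days, horizon = sch$horizon
          )
        }
      }))
    }))
  })
  emit("sensitivity", "sensitivity", sens)

  say("Selection-map area composition (a, f, k under each regimen)")
  area <- timed("area_composition", {
    bind_rows(lapply(c("a", "f", "k"), function(pm) {
      bind_rows(lapply(c("A", "B", "C"), function(reg) {
        vals <- default_sensitivity_values(
          tab, reg, pm,
          n_growth = g$area_values, n_mutation = g$area_values,
          growth_delta = g$sensitivity$growth_delta,
          mutation_range = g$sensitivity$mutation_range
        )
        selection_area_composition(
          tab, pm, reg,
          parameter_values = vals, n_grid = g$area_n,
          z0 = ini$z0, total = ini$total,
          switch_days = switch_days, horizon = sch$horizon
        )
      }))
    }))
  })
  emit("area_composition", "area_composition", area)

  finals <- vapply(trajs, function(tr) tr$total[nrow(tr)], numeric(1))
  recurrences <- vapply(trajs, recurrence_time, numeric(1))
  sweep_min <- sweeps |>
    group_by(.data$strategy) |>
    slice_min(.data$final_total, n = 1, with_ties = FALSE) |>
    ungroup()
  summary <- list(
    final_totals = as.list(finals),
    recurrence_days = as.list(recurrences),
    sweep_minima = setNames(as.list(sweep_min$final_total), sweep_min$strategy),
    sweep_argmin_day = setNames(as.list(sweep_min$switch_day), sweep_min$strategy),
    degeneracy_fallbacks = fallbacks,
    timings_sec = timings
  )
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest[[length(manifest) + 1L]] <- tibble(stage = "summary", file = summary_path)
  say("Wrote ", length(manifest), " files to ", out_dir,
    " (degeneracy fallbacks: ", fallbacks, ")")
  invisible(bind_rows(manifest))
}
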