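test_that("switch-time sweep locates the optimum and honors boundaries", {
  days <- seq(5, 995, by = 5)
  swA <- sweep_switch_time(tbl, "A-first", days)
  swB <- sweep_switch_time(tbl, "B-first", days)
  expect_equal(nrow(swA), length(days))
  expect_true(all(swA$final_total > 0))

  gA <- glance(swA)
  gB <- glance(swB)
  # B-first achieves a lower optimum than A-first
  expect_lt(gB$min_final, gA$min_final)
  # glance agrees with a direct scan
  expect_equal(gA$min_final, min(swA$final_total))
  expect_equal(gA$best_switch_day, swA$switch_day[which.min(swA$final_total)])

  # switching at day 0 is second-line monotherapy
  sw0 <- sweep_switch_time(tbl, "A-first", 0)
  expect_equal(sw0$final_total, final_total(tbl, monotherapy_schedule("B")),
    tolerance = 1e-12
  )
  expect_error(sweep_switch_time(tbl, "A-first", 1500), class = "tki_error_schedule")
})

test_that("acceptable switch windows are wide plateaus around the optimum", {
  days <- 1:999
  swA <- sweep_switch_time(tbl, "A-first", days)
  swB <- sweep_switch_time(tbl, "B-first", days)
  window <- function(sw) {
    ok <- sw$switch_day[sw$final_total <= 1.1 * min(sw$final_total)]
    c(min(ok), max(ok))
  }
  # A-first: a contiguous months-long window of near-optimal switch days
  # spanning the first treatment phase
  wA <- window(swA)
  expect_lte(wA[1], 100)
  expect_gte(wA[2], 300)
  expect_gte(wA[2] - wA[1], 200)
  # B-first: the within-10% window covers at least [250, 850] and is
  # broader than the A-first window
  wB <- window(swB)
  expect_lte(wB[1], 250)
  expect_gte(wB[2], 850)
  expect_gt(wB[2] - wB[1], wA[2] - wA[1])
})

test_that("proportion sweeps rise only for the strategy the genotype resists", {
  decades <- 10^(-8:-1)
  px <- sweep_initial_proportion(tbl, "X", proportions = decades)
  expect_s3_class(px, "tki_proportion_sweep")
  expect_equal(nrow(px), length(decades) * 3)
  th <- rise_thresholds(px)
  # A-first rises; the other strategies stay within 10% over the range
  expect_false(is.na(th$rise_threshold[th$strategy == "A-first"]))
  expect_lt(th$max_relative_rise[th$strategy == "B-first"], 0.1)
  expect_lt(th$max_relative_rise[th$strategy == "C"], 0.1)

  # varying the fraction of a type the strategy controls leaves the final
  # within 1% up to fractions of 1e-3
  sub <- px[px$proportion <= 1e-3 & px$strategy != "A-first", ]
  for (st in unique(sub$strategy)) {
    v <- sub$final_total[sub$strategy == st]
    expect_lt(max(v) / min(v) - 1, 0.01)
  }

  expect_error(
    sweep_initial_proportion(tbl, "X", proportions = c(0.5, 0.9999999)),
    class = "tki_error_composition"
  )
  expect_error(
    sweep_initial_proportion(tbl, "X", proportions = c(0.2, 0.1)),
    class = "tki_error_composition"
  )
})

test_that("a doubly resistant subclone raises the final under every strategy", {
  pz <- sweep_initial_proportion(tbl, "Z", proportions = 10^(-9:-5))
  th <- rise_thresholds(pz)
  expect_true(all(!is.na(th$rise_threshold)))
  expect_true(all(th$rise_threshold <= 1e-6))
})

test_that("selection map labels agree with independently recomputed finals", {
  xs <- 10^seq(-8, -1, length.out = 6)
  ys <- 10^seq(-8, -1, length.out = 6)
  map <- build_selection_map(tbl, xs, ys)
  expect_equal(nrow(map), 36)
  expect_true(all(abs(
    map$final_A_first - purrr::map2_dbl(map$x_prop, map$y_prop, function(fx, fy) {
      ini <- standard_initial_state(1e9, fx * 1e9, fy * 1e9, 10)
      final_total(tbl, strategy_schedule("A-first"), ini)
    })
  ) < 1e-3))
  recomputed <- apply(
    as.matrix(map[c("final_A_first", "final_B_first", "final_C")]), 1, which.min
  )
  expect_equal(map$best, c("A-first", "B-first", "C")[recomputed])
})

test_that("the optimal label shifts from B-first and never back along Y", {
  map <- build_selection_map(tbl,
    x_props = 1e-6, y_props = 10^seq(-8, -1, length.out = 15)
  )
  labels <- map$best[order(map$y_prop)]
  expect_equal(labels[1], "B-first")
  # once the label leaves B-first it never returns
  left <- which(labels != "B-first")
  if (length(left) > 0) {
    expect_true(all(labels[seq(min(left), length(labels))] != "B-first"))
  }
})

test_that("sensitivity grids are monotone where selection pressure says so", {
  vals <- seq(-0.27, -0.07, length.out = 7)
  sg <- parameter_sensitivity_grid(tbl, "a", "A-first",
    first_values = vals, second_values = c(-0.42, -0.32, -0.22)
  )
  expect_equal(nrow(sg), 21)
  # final total non-decreasing in a_A at every fixed a_B
  for (sv in unique(sg$second_value)) {
    col <- sg[sg$second_value == sv, ]
    expect_true(all(diff(col$final_total[order(col$first_value)]) >= 0))
  }
  # combination therapy: non-decreasing in f_C
  sc <- parameter_sensitivity_grid(tbl, "f", "C",
    values = seq(-0.05, 0.08, length.out = 9)
  )
  expect_true(all(is.na(sc$second_value)))
  expect_true(all(diff(sc$final_total[order(sc$first_value)]) >= 0))

  # a degenerate single-point grid reproduces the default final
  one <- parameter_sensitivity_grid(tbl, "b", "A-first",
    first_values = 0.045, second_values = -0.15
  )
  expect_equal(one$final_total, final_total(tbl, strategy_schedule("A-first")),
    tolerance = 1e-12
  )
  expect_error(
    parameter_sensitivity_grid(tbl, "zz", "A-first"),
    class = "tki_error_unknown_parameter"
  )
})

test_that("area compositions partition the map and respond to drug potency", {
  ac <- selection_area_composition(tbl, "k", "B",
    parameter_values = c(1e-8, 1e-7, 1e-6), n_grid = 7
  )
  sums <- tapply(ac$fraction, ac$value, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # at default-scale mutation rates B-first dominates the map
  bfrac <- ac$fraction[ac$strategy == "B-first" & ac$value <= 1e-7]
  expect_true(all(bfrac == tapply(
    ac$fraction[ac$value <= 1e-7], ac$value[ac$value <= 1e-7], max
  )))

  # weakening drug B against Type-W (a_B strongly positive) shrinks the
  # B-first region; verified against a brute-force 5x5 recomputation
  brute_frac <- function(params) {
    xs <- 10^seq(-8, -1, length.out = 5)
    n_b <- 0
    for (fx in xs) {
      for (fy in xs) {
        ini <- standard_initial_state(1e9, fx * 1e9, fy * 1e9, 10)
        finals <- c(
          final_total(params, strategy_schedule("A-first"), ini),
          final_total(params, strategy_schedule("B-first"), ini),
          final_total(params, strategy_schedule("C"), ini)
        )
        if (which.min(finals) == 2) n_b <- n_b + 1
      }
    }
    n_b / 25
  }
  weak_b <- set_rate(tbl, "B", "a", 0.1)
  expect_lt(brute_frac(weak_b), brute_frac(tbl))
  acw <- selection_area_composition(tbl, "a", "B",
    parameter_values = c(-0.32, 0.1), n_grid = 5
  )
  expect_lt(
    acw$fraction[acw$strategy == "B-first" & acw$value == 0.1],
    acw$fraction[acw$strategy == "B-first" & acw$value == -0.32]
  )
  expect_equal(
    acw$fraction[acw$strategy == "B-first" & acw$value == 0.1],
    brute_frac(weak_b)
  )
})

test_that("experiments are bit-identical across repeated runs", {
  m1 <- build_selection_map(tbl,
    x_props = 10^seq(-7, -2, length.out = 4),
    y_props = 10^seq(-7, -2, length.out = 4)
  )
  m2 <- build_selection_map(tbl,
    x_props = 10^seq(-7, -2, length.out = 4),
    y_props = 10^seq(-7, -2, length.out = 4)
  )
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  s1 <- sweep_switch_time(tbl, "B-first", seq(100, 900, 100))
  s2 <- sweep_switch_time(tbl, "B-first", seq(100, 900, 100))
  expect_identical(s1$final_total, s2$final_total)
})
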