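test_that("zero-mutation dynamics decouple into pure exponentials", {
  p0 <- tbl
  p0[c("g", "h", "k", "p", "q")] <- 0
  s0 <- tumor_state(1e9, 2e4, 3e3, 10)
  for (reg in c("A", "B", "C")) {
    r <- regimen_rates(p0, reg)
    out <- closed_form_state(p0, s0, reg, 10)
    expect_equal(
      state_vec(out),
      c(1e9 * exp(r$a * 10), 2e4 * exp(r$b * 10), 3e3 * exp(r$c * 10), 10 * exp(r$f * 10)),
      tolerance = 1e-14
    )
  }
  # a pure Type-W tumor stays pure
  w_only <- closed_form_state(p0, tumor_state(1e9, 0, 0, 0), "A", 10)
  expect_equal(state_vec(w_only), c(1e9 * exp(-1.7), 0, 0, 0), tolerance = 1e-14)
})

test_that("zero elapsed time and frozen dynamics are identities", {
  out0 <- closed_form_state(tbl, std, "B", 0)
  expect_equal(state_vec(out0), state_vec(std))
  expect_equal(state_vec(numeric_reference_state(tbl, std, "B", 0)), state_vec(std))

  frozen <- tbl
  frozen[c("a", "b", "c", "f", "g", "h", "k", "p", "q")] <- 0
  out <- numeric_reference_state(frozen, std, "A", 500)
  expect_equal(state_vec(out), state_vec(std), tolerance = 1e-10)
  expect_equal(state_vec(closed_form_state(frozen, std, "A", 500)),
    state_vec(std),
    tolerance = 1e-12
  )
})

test_that("closed form matches the adaptive ODE reference at the defaults", {
  for (reg in c("A", "B", "C")) {
    for (dt in c(307, 567, 1000)) {
      cf <- closed_form_state(tbl, std, reg, dt)
      nm <- numeric_reference_state(tbl, std, reg, dt, rel_tol = 1e-10)
      expect_lt(rel_err(state_vec(cf), state_vec(nm)), 1e-6)
    }
  }
})

test_that("closed form matches the ODE reference on seeded random scenarios", {
  scen <- sample_scenarios(scenario_config(seed = 101), n = 25)
  for (i in seq_len(nrow(scen))) {
    pars <- scen$params[[i]]
    ini <- scen$initial[[i]]
    reg <- c("A", "B", "C")[(i - 1) %% 3 + 1]
    for (dt in c(10, 100, 1000)) {
      cf <- closed_form_state(pars, ini, reg, dt)
      nm <- numeric_reference_state(pars, ini, reg, dt, rel_tol = 1e-10)
      expect_lt(rel_err(state_vec(cf), state_vec(nm)), 1e-6)
    }
  }
})

test_that("the propagator is linear in the initial state", {
  s1 <- tumor_state(5e8, 1e4, 2e4, 10)
  s2 <- tumor_state(1e8, 7e3, 1e2, 3)
  alpha <- 0.3
  beta <- 1.7
  combo <- tumor_state(
    alpha * s1$w + beta * s2$w, alpha * s1$x + beta * s2$x,
    alpha * s1$y + beta * s2$y, alpha * s1$z + beta * s2$z
  )
  for (reg in c("A", "B")) {
    lhs <- state_vec(closed_form_state(tbl, combo, reg, 200))
    rhs <- alpha * state_vec(closed_form_state(tbl, s1, reg, 200)) +
      beta * state_vec(closed_form_state(tbl, s2, reg, 200))
    expect_lt(rel_err(lhs, rhs), 1e-9)
  }
})

test_that("advancing satisfies the semigroup property", {
  for (reg in c("A", "B", "C")) {
    two_step <- closed_form_state(
      tbl, closed_form_state(tbl, std, reg, 123.5), reg, 276.5
    )
    one_step <- closed_form_state(tbl, std, reg, 400)
    expect_lt(rel_err(state_vec(two_step), state_vec(one_step)), 1e-9)
    expect_equal(two_step$time, one_step$time)
  }
})

test_that("non-negative inputs stay non-negative", {
  scen <- sample_scenarios(scenario_config(seed = 77), n = 10)
  for (i in seq_len(nrow(scen))) {
    out <- closed_form_state(scen$params[[i]], scen$initial[[i]], "A", 500)
    expect_true(all(state_vec(out) >= 0))
  }
  # boundary: empty compartments
  out <- closed_form_state(tbl, tumor_state(0, 0, 0, 0), "B", 100)
  expect_equal(state_vec(out), c(0, 0, 0, 0))
})

test_that("the day-1000 total is monotone in every rate", {
  base_total <- state_total(closed_form_state(tbl, std, "A", 1000))
  for (nm in c("a", "b", "c", "f")) {
    bumped <- set_rate(tbl, "A", nm, regimen_rates(tbl, "A")[[nm]] + 0.01)
    expect_gte(state_total(closed_form_state(bumped, std, "A", 1000)), base_total)
  }
  for (nm in c("g", "h", "k", "p", "q")) {
    bumped <- set_rate(tbl, "A", nm, 1e-6)
    expect_gte(state_total(closed_form_state(bumped, std, "A", 1000)), base_total)
  }
})

test_that("near-coincident rates fall back to integration, matching expm", {
  skip_if_not_installed("Matrix")
  degen <- set_rate(tbl, "A", "b", -0.17) # b == a
  expect_message(
    out <- closed_form_state(degen, std, "A", 50),
    class = "tki_degenerate_fallback"
  )
  r <- regimen_rates(degen, "A")
  M <- matrix(
    c(
      r$a, 0, 0, 0,
      r$g, r$b, 0, 0,
      r$h, 0, r$c, 0,
      r$k, r$p, r$q, r$f
    ),
    nrow = 4, byrow = TRUE
  )
  expected <- as.numeric(Matrix::expm(M * 50) %*% state_vec(std))
  expect_lt(rel_err(state_vec(out), expected), 1e-8)
})

test_that("negative durations are rejected", {
  expect_error(closed_form_state(tbl, std, "A", -1), class = "tki_error_state")
  expect_error(numeric_reference_state(tbl, std, "A", -1), class = "tki_error_state")
})
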