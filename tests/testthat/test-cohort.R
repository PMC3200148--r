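test_that("npv follows the year-indexed discounting convention", {
  expect_equal(npv(rep(1, 10), 0), 10)
  expect_equal(npv(1, 0.04), 1 / 1.04, tolerance = 1e-10)
  expect_equal(npv(numeric(0), 0.05), 0)
  expect_equal(npv(1, 0.04, first_year = 0), 1)  # year-0 amounts undiscounted
  expect_error(npv(c(1, Inf), 0.04), "finite")
})

test_that("the simulator matches the 2-state geometric closed form to 1e-9", {
  for (s in c(0.9, 0.97)) {
    for (r in c(0, 0.015, 0.04)) {
      m <- two_state_model(s)
      a <- s / (1 + r)
      # end-of-cycle convention: discounted life expectancy sum_k (s/(1+r))^k
      sim <- simulate_cohort(m, NULL, 30, discount_spec(r, r), half_cycle = FALSE)
      expect_equal(sim$qalys, a / (1 - a), tolerance = 1e-9)
      # half-cycle (trapezoid) convention: (1+s) / (2(1+r)) / (1 - s/(1+r))
      simh <- simulate_cohort(m, NULL, 30, discount_spec(r, r), half_cycle = TRUE)
      expect_equal(simh$qalys, (1 + s) / (2 * (1 + r)) / (1 - a), tolerance = 1e-9)
    }
  }
})

test_that("immediate extinction yields the half-cycle-corrected first year", {
  m <- two_state_model(0)  # everyone dies in the first cycle
  sim <- simulate_cohort(m, NULL, 30, discount_spec(0, 0), half_cycle = TRUE)
  expect_equal(sim$qalys, 0.5)
  sim0 <- simulate_cohort(m, NULL, 30, discount_spec(0, 0), half_cycle = FALSE)
  expect_equal(sim0$qalys, 0)
})

test_that("QALY and cost NPVs are non-increasing in their discount rates", {
  m <- default_cohort_model("general")
  rates <- c(0, 0.01, 0.015, 0.03, 0.04, 0.06)
  q <- vapply(rates, function(r)
    simulate_cohort(m, NULL, 55, discount_spec(r, 0.04))$qalys, numeric(1))
  expect_true(all(diff(q) < 0))
  co <- vapply(rates, function(r)
    simulate_cohort(m, NULL, 55, discount_spec(0.015, r))$costs, numeric(1))
  expect_true(all(diff(co) < 0))
})

test_that("truncating the horizon never increases absolute outcomes", {
  m <- default_cohort_model("diabetes")
  horizons <- c(10, 25, 50, "lifetime")
  res <- lapply(horizons, function(h)
    simulate_cohort(m, NULL, 55, discount_spec(0.015, 0.04, if (h == "lifetime") h else as.numeric(h))))
  q <- vapply(res, function(x) x$qalys, numeric(1))
  co <- vapply(res, function(x) x$costs, numeric(1))
  expect_true(all(diff(q) >= 0))
  expect_true(all(diff(co) >= 0))
})

test_that("a non-stochastic or invalid model is rejected", {
  expect_error(
    cohort_model(function(age) matrix(c(0.5, 0.4, 0.2,
                                        0, 0.5, 0.5,
                                        0, 0, 1), 3, 3, byrow = TRUE),
                 function(age) c(1, 0.5, 0), function(age) c(0, 0, 0)),
    "do not sum to 1")
  expect_error(
    cohort_model(function(age) matrix(c(0.5, 0.3, 0.2,
                                        0, 0.5, 0.5,
                                        0.1, 0, 0.9), 3, 3, byrow = TRUE),
                 function(age) c(1, 0.5, 0), function(age) c(0, 0, 0)),
    "absorbing")
  m <- cohort_model(function(age) matrix(c(0.9, 0.05, 0.05,
                                           0, 0.5, 0.5,
                                           0, 0, 1), 3, 3, byrow = TRUE),
                    function(age) c(1.2, 0.5, 0), function(age) c(0, 0, 0))
  expect_error(simulate_cohort(m, NULL, 50), "\\[0, 1\\]")
})

test_that("evaluate_cell is zero at the null effect and additive in cost streams", {
  m <- default_cohort_model("general")
  null_eff <- intervention_effect(1, 1, 10, 0, 0)
  ev0 <- evaluate_cell(m, null_eff, 55)
  expect_equal(ev0$qaly, 0, tolerance = 1e-12)
  expect_equal(ev0$cost, 0, tolerance = 1e-12)

  # pure cost effect: q stays 0, c is the discounted survival-weighted stream
  cost_eff <- intervention_effect(1, 1, 0, 250, 5)
  ev1 <- evaluate_cell(m, cost_eff, 55)
  expect_equal(ev1$qaly, 0, tolerance = 1e-12)
  sim <- simulate_cohort(m, NULL, 55)
  occ <- c(1, 0, 0)
  expected <- 0
  age <- 55
  for (k in 0:4) {
    expected <- expected + 250 * (occ[1] + occ[2]) / 1.04^k
    occ <- as.vector(occ %*% m$transition(age))
    age <- age + 1
  }
  expect_equal(ev1$cost, expected, tolerance = 1e-10)

  # doubling the annual cost doubles the cost and leaves QALYs untouched
  ev2 <- evaluate_cell(m, intervention_effect(1, 1, 0, 500, 5), 55)
  expect_equal(ev2$cost, 2 * ev1$cost, tolerance = 1e-12)

  # additivity on top of a protective effect
  prot <- intervention_effect(0.8, 0.95, 10, 0, 0)
  prot_c <- intervention_effect(0.8, 0.95, 10, 100, 5)
  a <- evaluate_cell(m, prot, 55)
  b <- evaluate_cell(m, prot_c, 55)
  expect_equal(b$qaly, a$qaly, tolerance = 1e-12)
  expect_gt(b$cost, a$cost)
})

test_that("a protective mortality effect gains QALYs and accrues care costs", {
  # positive care costs, no disease pathway: longer life must cost more
  m <- cohort_model(
    transition = function(age) {
      pd <- min(0.5, 0.002 * exp(0.07 * age))
      matrix(c(1 - pd, 0, pd, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE)
    },
    utility = function(age) c(max(0.6, 0.9 - 0.002 * age), 0, 0),
    care_cost = function(age) c(1000, 0, 0)
  )
  eff <- intervention_effect(1, 0.7, 15, 0, 0)
  ev <- evaluate_cell(m, eff, 55)
  expect_gt(ev$qaly, 0)
  expect_gt(ev$cost, 0)
  # cross-check against the two-state closed form with a constant hazard
  s <- 0.95; mlt <- 0.8; r <- 0.03
  m2 <- two_state_model(s)
  ev2 <- evaluate_cell(m2, intervention_effect(1, mlt, Inf, 0, 0), 30,
                       discount_spec(r, r), half_cycle = FALSE)
  st <- 1 - (1 - (1 - s))^mlt  # death prob under the hazard multiplier
  at <- (1 - st) / (1 + r); ac <- s / (1 + r)
  expect_equal(ev2$qaly, at / (1 - at) - ac / (1 - ac), tolerance = 1e-9)
})
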