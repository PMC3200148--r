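test_that("zero budget with positive costs funds nobody", {
  pb <- mk_problem(q = c(2, 1), cost = c(100, 100), dem = c(10, 10),
                   cap = c(Inf, Inf), codes = c("A", "B"))
  al <- solve_allocation(pb, 0)
  expect_equal(al$total_qalys, 0)
  expect_equal(al$spend, 0)
  expect_true(all(al$participants$participants == 0))
})

test_that("the better of two equal-cost programs is funded first", {
  pb <- mk_problem(q = c(2, 1), cost = c(100, 100), dem = c(10, 10),
                   cap = c(Inf, Inf), codes = c("A", "B"))
  al <- solve_allocation(pb, 500)
  expect_equal(al$total_qalys, 10, tolerance = 1e-9)
  expect_equal(al$participants$participants[al$participants$code == "A"], 5,
               tolerance = 1e-9)
  expect_equal(al$participants$participants[al$participants$code == "B"], 0)
  o <- oracle_solve(pb, 500)
  expect_equal(o$objective, al$total_qalys, tolerance = 1e-9)
})

test_that("binding capacity splits across ages with the youngest-first tie-break", {
  pb <- mk_problem(q = c(2, 2), cost = c(100, 100), dem = c(10, 10), cap = 12)
  al <- solve_allocation(pb, 10000)
  expect_equal(sum(al$participants$participants), 12, tolerance = 1e-9)
  expect_equal(al$total_qalys, 24, tolerance = 1e-9)
  expect_equal(al$spend, 1200, tolerance = 1e-9)
  # tie between identical ages resolves to the younger one first
  expect_equal(al$participants$participants, c(10, 2), tolerance = 1e-9)
  expect_true(any(grepl("capacity:P01", al$binding)))
  o <- oracle_solve(pb, 10000)
  expect_equal(o$objective, 24, tolerance = 1e-9)
})

test_that("a single cell is funded fractionally at half its full cost", {
  pb <- mk_problem(q = 1, cost = 100, dem = 10, cap = Inf)
  al <- solve_allocation(pb, 500)
  expect_equal(al$participants$participants, 5, tolerance = 1e-12)
  o <- oracle_solve(pb, 500)
  expect_equal(o$x, 5, tolerance = 1e-9)
})

test_that("a budget covering all demand reaches the box optimum", {
  pb <- mk_problem(q = c(1, 2), cost = c(10, 20), dem = c(5, 5),
                   cap = c(Inf, Inf))
  o <- oracle_solve(pb, 1e6)
  expect_equal(o$objective, 15, tolerance = 1e-12)
  al <- solve_allocation(pb, 1e6)
  expect_equal(al$total_qalys, 15, tolerance = 1e-12)
  expect_false("budget" %in% al$binding)
})

test_that("solve_allocation matches the enumeration oracle on random instances", {
  set.seed(101)
  for (i in 1:60) {
    inst <- random_small_problem()
    o <- oracle_solve(inst$problem, inst$budget)
    s <- solve_allocation(inst$problem, inst$budget)
    expect_true(o$feasible)
    expect_equal(s$total_qalys, o$objective,
                 tolerance = 1e-6 * max(1, abs(o$objective)))
    # feasibility of the returned allocation
    p <- s$participants
    expect_true(all(p$participants >= -1e-9))
    expect_true(all(p$participants <= p$demand + 1e-9 * pmax(1, p$demand)))
    expect_lte(s$spend, inst$budget + 1e-7 * max(1, inst$budget))
    caps <- inst$problem$capacities
    used <- tapply(p$participants, p$code, sum)
    expect_true(all(used <= caps$capacity[match(names(used), caps$code)] +
                      1e-7 * pmax(1, caps$capacity[match(names(used), caps$code)])))
  }
})

test_that("solve_allocation agrees with an independent simplex implementation", {
  skip_if_not_installed("boot")
  set.seed(77)
  for (i in 1:10) {
    inst <- random_free_problem(np = 4, na = 3)
    mats_cells <- problem_cells(inst$problem)
    q <- mats_cells$qaly_per_participant
    cost <- mats_cells$cost_per_participant
    dem <- mats_cells$demand
    n <- length(q)
    A1 <- rbind(cost, diag(n))
    b1 <- c(inst$budget, dem)
    ref <- boot::simplex(a = q, A1 = A1, b1 = b1, maxi = TRUE)
    s <- solve_allocation(inst$problem, inst$budget)
    expect_equal(s$total_qalys, ref$value,
                 tolerance = 1e-6 * max(1, abs(ref$value)))
  }
})

test_that("greedy_solve equals the LP on capacity-free problems and obeys guards", {
  pb <- two_ratio_problem()
  g <- greedy_solve(pb, 700)
  expect_equal(g$total_qalys, 6, tolerance = 1e-12)
  s <- solve_allocation(pb, 700)
  expect_equal(g$total_qalys, s$total_qalys, tolerance = 1e-9)
  expect_equal(greedy_solve(pb, 0)$total_qalys, 0)

  # equal ratios fund in lexicographic (program code, age) order
  pb2 <- mk_problem(q = c(1, 1), cost = c(100, 100), dem = c(3, 3),
                    cap = c(Inf, Inf), codes = c("B", "A"))
  g2 <- greedy_solve(pb2, 300)
  expect_equal(g2$participants$participants[g2$participants$code == "A"], 3)
  expect_equal(g2$participants$participants[g2$participants$code == "B"], 0)

  capped <- mk_problem(q = 1, cost = 10, dem = 5, cap = 3)
  expect_error(greedy_solve(capped, 100), "solve_allocation")
  neg <- mk_problem(q = c(1, -1), cost = c(10, 10), dem = c(5, 5),
                    cap = c(Inf, Inf))
  expect_error(greedy_solve(neg, 100), "q > 0")
})

test_that("greedy matches the LP to 1e-9 on random capacity-free instances", {
  set.seed(202)
  for (i in 1:40) {
    inst <- random_free_problem(np = sample(2:5, 1), na = sample(1:3, 1))
    g <- greedy_solve(inst$problem, inst$budget)
    s <- solve_allocation(inst$problem, inst$budget)
    expect_equal(g$total_qalys, s$total_qalys,
                 tolerance = 1e-9 * max(1, abs(g$total_qalys)))
  }
})

test_that("shadow prices match frontier slopes and finite differences", {
  pb <- mk_problem(q = c(2, 1), cost = c(100, 100), dem = c(10, 10),
                   cap = c(Inf, Inf), codes = c("A", "B"))
  # interior of the first segment: program A costs 50 euro per QALY
  sp <- shadow_prices(pb, 500)
  expect_equal(sp$budget_price, 2 / 100, tolerance = 1e-9)
  # non-binding budget: price zero
  sp2 <- shadow_prices(pb, 1e6)
  expect_equal(sp2$budget_price, 0)
  # interior of the first segment of the 100-vs-200 euro/QALY construction:
  # one marginal euro buys 1/100 QALY
  expect_equal(shadow_prices(two_ratio_problem(), 300)$budget_price, 0.01,
               tolerance = 1e-9)

  # capacity price via the worked capacity example: one more unit of capacity
  # is worth one more participant at q = 2
  cap_pb <- mk_problem(q = c(2, 2), cost = c(100, 100), dem = c(10, 10), cap = 12)
  sp3 <- shadow_prices(cap_pb, 10000)
  expect_equal(sp3$capacity$price, 2, tolerance = 1e-9)

  # budget dual equals the forward finite-difference slope away from corners
  set.seed(303)
  for (i in 1:8) {
    inst <- random_small_problem(allow_cost_saving = FALSE)
    b <- inst$budget
    if (b <= 0) next
    s <- solve_allocation(inst$problem, b)
    db <- 1e-3 * max(b, 1)
    s2 <- solve_allocation(inst$problem, b + db)
    fd <- (s2$total_qalys - s$total_qalys) / db
    dual_mid <- solve_allocation(inst$problem, b + db / 2)$duals$budget
    # compare the dual at the interval midpoint with the finite difference;
    # equality can only fail if a corner lies inside the interval, in which
    # case the dual at the midpoint still brackets the difference quotient
    expect_true(fd <= s$duals$budget + 1e-4 * max(1, fd))
    expect_true(fd >= s2$duals$budget - 1e-4 * max(1, fd))
    expect_true(abs(dual_mid - fd) <= 1e-4 * max(1, abs(fd)) ||
                  s$duals$budget > s2$duals$budget)
  }
})

test_that("max_health_min_cost finds the cheapest full-health endpoint", {
  pb <- mk_problem(q = c(1, 2), cost = c(10, 20), dem = c(5, 8),
                   cap = c(Inf, Inf))
  end <- max_health_min_cost(pb)
  expect_equal(end$total_qalys, 1 * 5 + 2 * 8, tolerance = 1e-9)
  expect_equal(end$spend, 10 * 5 + 20 * 8, tolerance = 1e-9)

  # capped program with equal q but different c: cap filled with the cheaper age
  pb2 <- mk_problem(q = c(2, 2), cost = c(50, 100), dem = c(10, 10), cap = 12)
  end2 <- max_health_min_cost(pb2)
  expect_equal(end2$total_qalys, 24, tolerance = 1e-9)
  expect_equal(end2$spend, 10 * 50 + 2 * 100, tolerance = 1e-9)
  o <- oracle_solve(pb2, end2$spend)
  expect_equal(o$objective, 24, tolerance = 1e-9)

  # dominated cells stay unfunded
  pb3 <- mk_problem(q = c(1, -0.5), cost = c(10, 10), dem = c(5, 5),
                    cap = c(Inf, Inf))
  end3 <- max_health_min_cost(pb3)
  expect_equal(end3$participants$participants[2], 0)
  expect_equal(end3$total_qalys, 5, tolerance = 1e-9)
})

test_that("total QALYs are monotone in the budget", {
  set.seed(404)
  pb <- generate_problem(seed = 5, n_programs = 4)
  budgets <- seq(0, 1.1 * max_health_min_cost(pb)$spend, length.out = 12)
  vals <- vapply(budgets, function(b) solve_allocation(pb, b)$total_qalys,
                 numeric(1))
  expect_true(all(diff(vals) >= -1e-6 * pmax(1, vals[-1])))
})

test_that("removing capacities never lowers the objective at any budget", {
  pb <- generate_problem(seed = 9, n_programs = 4, capacity_tightness = 0.5)
  free <- drop_capacities(pb)
  for (b in c(1e6, 1e7, 1e8, 1e9)) {
    expect_gte(solve_allocation(free, b)$total_qalys,
               solve_allocation(pb, b)$total_qalys - 1e-6)
  }
})

test_that("oracle_solve enforces its size guard and negative budgets behave", {
  big <- mk_problem(q = rep(1, 8), cost = rep(10, 8), dem = rep(5, 8),
                    cap = rep(Inf, 4))
  expect_error(oracle_solve(big, 100), "guarded")

  pb <- mk_problem(q = 1, cost = 100, dem = 10, cap = Inf)
  al <- solve_allocation(pb, -50)
  expect_equal(al$status, "infeasible")
  # with a cost-saving cell a negative budget is feasible
  pb2 <- mk_problem(q = c(1, 1), cost = c(-100, 50), dem = c(10, 10),
                    cap = c(Inf, Inf))
  al2 <- solve_allocation(pb2, -50)
  expect_equal(al2$status, "optimal")
  expect_gt(al2$total_qalys, 0)
  o2 <- oracle_solve(pb2, -50)
  expect_equal(al2$total_qalys, o2$objective, tolerance = 1e-9)
})
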