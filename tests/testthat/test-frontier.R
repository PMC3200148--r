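test_that("a single cell yields one segment with its own ICER", {
  pb <- mk_problem(q = 1, cost = 1, dem = 10, cap = Inf)
  fr <- trace_frontier(pb)
  expect_equal(nrow(fr$segments), 1)
  expect_equal(fr$segments$b_lo, 0)
  expect_equal(fr$segments$b_hi, 10, tolerance = 1e-9)
  expect_equal(fr$segments$icer, 1, tolerance = 1e-9)
  expect_equal(fr$endpoint$budget, 10, tolerance = 1e-9)
  expect_equal(fr$endpoint$qalys, 10, tolerance = 1e-9)
})

test_that("the two-ratio construction breaks at 0, 500, 900 with ICERs 100, 200", {
  fr <- trace_frontier(two_ratio_problem())
  expect_equal(nrow(fr$segments), 2)
  expect_equal(fr$segments$b_lo, c(0, 500), tolerance = 1e-6)
  expect_equal(fr$segments$b_hi, c(500, 900), tolerance = 1e-6)
  expect_equal(fr$segments$icer, c(100, 200), tolerance = 1e-6)
  expect_equal(fr$endpoint$qalys, 7, tolerance = 1e-9)
  # entering bookkeeping: A first, then B
  expect_equal(fr$segments$entering[[1]], "A1")
  expect_equal(fr$segments$entering[[2]], "B1")
  # endpoint average CER: 900 euro buys all 7 QALYs (5 from A, 2 from B)
  end <- average_cer_of_endpoint(two_ratio_problem())
  expect_equal(end$raw, 900 / 7, tolerance = 1e-9)
})

test_that("frontier slopes decrease strictly and match direct solves", {
  pb <- generate_problem(seed = 3, n_programs = 4)
  fr <- trace_frontier(pb)
  expect_true(all(diff(fr$segments$slope) < 0))
  expect_true(all(diff(fr$segments$icer) > 0))
  # contiguity
  expect_equal(fr$segments$b_lo[-1], fr$segments$b_hi[-nrow(fr$segments)],
               tolerance = 1e-9)
  grid <- seq(0, fr$endpoint$budget, length.out = 50)
  direct <- vapply(grid, function(b) solve_allocation(pb, b)$total_qalys,
                   numeric(1))
  expect_equal(frontier_value(fr, grid), direct,
               tolerance = 1e-6)
})

test_that("no random feasible allocation beats the frontier", {
  set.seed(42)
  pb <- generate_problem(seed = 3, n_programs = 4)
  fr <- trace_frontier(pb)
  cl <- pb$cells
  caps <- pb$capacities
  for (i in 1:25) {
    p <- stats::runif(nrow(cl), 0, 1) * cl$demand
    # project onto the capacity constraints
    for (j in caps$program_id) {
      idx <- cl$program_id == j
      tot <- sum(p[idx])
      if (tot > caps$capacity[caps$program_id == j]) {
        p[idx] <- p[idx] * caps$capacity[caps$program_id == j] / tot
      }
    }
    spend <- sum(p * cl$cost)
    qal <- sum(p * cl$qaly)
    expect_lte(qal, frontier_value(fr, spend) + 1e-6 * max(1, qal))
  }
})

test_that("funded sets evolve by the recorded entering and leaving cells", {
  pb <- generate_problem(seed = 4, n_programs = 4)
  fr <- trace_frontier(pb)
  funded <- fr$baseline$funded
  for (i in seq_len(nrow(fr$segments))) {
    funded <- setdiff(union(funded, fr$segments$entering[[i]]),
                      fr$segments$leaving[[i]])
    mid <- (fr$segments$b_lo[i] + fr$segments$b_hi[i]) / 2
    al <- solve_allocation(pb, mid)
    now <- al$participants$short_name[al$participants$participants > 1e-7]
    expect_setequal(funded, now)
  }
})

test_that("cells can leave the optimal set as the budget grows", {
  # one capacity-constrained program whose cheap age is displaced by its
  # more effective age once money allows, plus fillers on either side
  pb <- mk_problem(
    q = c(1, 2, 0.5, 0.4, 0.1, 0.05), cost = c(10, 100, 20, 30, 50, 60),
    dem = c(10, 10, 20, 10, 10, 10), cap = c(10, Inf, Inf),
    codes = c("P", "Q", "R")
  )
  lo <- solve_allocation(pb, 100)
  expect_equal(lo$participants$participants[1], 10, tolerance = 1e-7)
  hi <- solve_allocation(pb, 5000)
  expect_equal(hi$participants$participants[1], 0, tolerance = 1e-7)
  expect_equal(hi$participants$participants[2], 10, tolerance = 1e-7)
  fr <- trace_frontier(pb)
  expect_true("P1" %in% unlist(fr$segments$leaving))
})

test_that("summaries report split percentages, ICERs and saturation", {
  pb <- generate_problem(seed = 2, n_programs = 4)
  fr <- trace_frontier(pb)
  b <- fr$endpoint$budget / 3
  sm <- summarize_allocation(pb, b, frontier = fr)
  expect_true(sm$pct_spend_general >= 0 && sm$pct_spend_general <= 100)
  expect_true(sm$pct_qaly_general >= 0 && sm$pct_qaly_general <= 100)
  # percentages recompute from the cell-level allocation
  al <- solve_allocation(pb, b)
  gen <- al$participants$population == "general"
  expect_equal(sm$pct_spend_general, 100 * sum(al$participants$spend[gen]) / al$spend,
               tolerance = 1e-9)
  # ICER comes from the segment containing the budget
  seg <- fr$segments
  i <- max(which(seg$b_lo < b))
  expect_equal(sm$icer, seg$icer[i])

  sm0 <- summarize_allocation(pb, 0)
  expect_true(sm0$undefined)
  expect_equal(sm0$total_qalys, 0)
  expect_true(is.na(sm0$pct_spend_general))

  smx <- summarize_allocation(pb, 2 * fr$endpoint$budget, frontier = fr)
  expect_true(smx$saturated)
  expect_equal(smx$total_qalys, fr$endpoint$qalys, tolerance = 1e-6)
})

test_that("a diabetes-only problem spends nothing in the general population", {
  pb <- mk_problem(q = c(1, 1), cost = c(10, 20), dem = c(5, 5),
                   cap = c(Inf, Inf), populations = c("diabetes", "diabetes"))
  sm <- summarize_allocation(pb, 60)
  expect_equal(sm$pct_spend_general, 0)
  expect_equal(sm$pct_qaly_general, 0)
})

test_that("entering/leaving formatting follows the +/- short-code style", {
  pb <- two_ratio_problem()
  sm <- summarize_allocation(pb, 700, reference_budget = 300)
  expect_equal(sm$entering[[1]], "B1")
  expect_match(sm$changes, "^\\+ B1")
})

test_that("endpoint average CER requires positive health gains", {
  pb <- mk_problem(q = -1, cost = 10, dem = 5, cap = Inf)
  expect_error(average_cer_of_endpoint(pb), "undefined")
})
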