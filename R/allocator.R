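# The allocation LP. With participants p_ja per program j and age group a,
# per-participant QALY gains q_ja and costs c_ja (net present values), the
# allocator maximizes total QALYs  sum_ja p_ja q_ja  subject to the budget
# sum_ja p_ja c_ja <= b, per-program capacity sum_a p_ja <= cap_j, and the
# demand boxes 0 <= p_ja <= dem_ja. Participants are continuous (fractional
# funding), so this is a linear program; its optimal value as a function of
# the budget is the concave piecewise-linear efficiency frontier.

problem_matrices <- function(problem) {
  cl <- problem$cells
  if (anyNA(cl$qaly) || anyNA(cl$cost)) {
    stop("problem cells carry no (qaly, cost) outcomes; the optimizer needs a ",
         "full problem, not a league-table stub (see fixture_problem() or ",
         "generate_problem())", call. = FALSE)
  }
  cp <- problem$capacities
  fin <- which(is.finite(cp$capacity))
  n <- nrow(cl)
  A_cap <- NULL
  if (length(fin) > 0) {
    A_cap <- matrix(0, length(fin), n)
    for (i in seq_along(fin)) {
      A_cap[i, cl$program_id == cp$program_id[fin[i]]] <- 1
    }
  }
  list(
    q = cl$qaly, cost = cl$cost, demand = cl$demand,
    A_cap = A_cap, cap_rhs = cp$capacity[fin], cap_codes = cp$code[fin],
    cells = cl, capacities = cp
  )
}

# fast path used by the frontier tracer: returns bare solver output
solve_core <- function(mats, budget) {
  A <- rbind(mats$cost, mats$A_cap)
  rhs <- c(budget, mats$cap_rhs)
  res <- lp_box_simplex(mats$q, A, rhs, mats$demand)
  if (res$status == "optimal") {
    res$x <- pmin(pmax(res$x, 0), mats$demand)
    res$budget_dual <- max(res$duals[1], 0)
  }
  res
}

build_allocation <- function(mats, budget, res, problem) {
  cl <- mats$cells
  if (res$status != "optimal") {
    return(structure(list(participants = NULL, budget = budget,
                          spend = NA_real_, total_qalys = NA_real_,
                          status = res$status, binding = character(0),
                          degenerate = FALSE, duals = NULL),
                     class = "allocation"))
  }
  p <- res$x
  spend <- sum(p * mats$cost)
  qalys <- sum(p * mats$q)

  scale_b <- max(1, abs(budget))
  tol_person <- 1e-7
  binding <- character(0)
  if (spend >= budget - 1e-7 * scale_b) binding <- c(binding, "budget")
  cap_duals <- stats::setNames(rep(0, nrow(mats$capacities)), mats$capacities$code)
  if (!is.null(mats$A_cap)) {
    used <- as.vector(mats$A_cap %*% p)
    bind_cap <- used >= mats$cap_rhs - tol_person * pmax(1, mats$cap_rhs)
    binding <- c(binding, paste0("capacity:", mats$cap_codes[bind_cap]))
    cap_duals[mats$cap_codes] <- pmax(res$duals[-1], 0)
  }
  at_dem <- p >= mats$demand - tol_person * pmax(1, mats$demand)
  binding <- c(binding, paste0("demand:", cl$short_name[at_dem]))
  dem_dual <- pmax(res$reduced, 0) * as.numeric(at_dem)

  participants <- tibble(
    short_name = cl$short_name, code = cl$code, age_label = cl$age_label,
    population = cl$population, participants = p, demand = cl$demand,
    spend = p * mats$cost, qalys = p * mats$q
  )
  duals <- list(
    budget = res$budget_dual,
    capacity = tibble(code = mats$capacities$code,
                      price = unname(cap_duals[mats$capacities$code])),
    demand = tibble(short_name = cl$short_name, price = dem_dual)
  )
  structure(list(participants = participants, budget = budget, spend = spend,
                 total_qalys = qalys, status = "optimal", binding = binding,
                 degenerate = isTRUE(res$degenerate), duals = duals),
            class = "allocation")
}

#' @export
print.allocation <- function(x, ...) {
  cat("<allocation> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat(sprintf("  budget %s, spend %s, total QALYs %s\n",
                format(x$budget, big.mark = ","),
                format(round(x$spend, 2), big.mark = ","),
                format(round(x$total_qalys, 2), big.mark = ",")))
    funded <- x$participants$short_name[x$participants$participants > 1e-7]
    cat("  funded cells: ", paste(funded, collapse = ", "), "\n", sep = "")
    cat("  budget shadow price: ", signif(x$duals$budget, 6), " QALY/euro\n", sep = "")
  }
  invisible(x)
}

#' Solve the allocation problem for a fixed budget
#'
#' Maximizes total QALYs over continuous participant numbers subject to the
#' budget, per-program capacity limits and per-cell demand limits. Returns an
#' optimal vertex solution; deterministic for a given problem and budget
#' (fixed pivoting rules, no randomization). Participant values are clipped
#' to `[0, demand]` after the solve as tolerance cleanup.
#'
#' @param problem A validated [allocation_problem()] with per-cell outcomes.
#' @param budget Available budget `b` in euro (net present value). A negative
#'   budget is infeasible unless cost-saving cells exist.
#' @return An object of class `allocation`: cell-level participants, spend
#'   and QALYs, total spend and QALYs, solver `status` (`"optimal"` or
#'   `"infeasible"`), the set of `binding` constraints, a primal-degeneracy
#'   flag, and `duals` (shadow prices of the budget, capacities and demands).
#' @export
solve_allocation <- function(problem, budget) {
  viol <- validate_problem(problem)
  if (length(viol) > 0) {
    stop("invalid problem:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  stopifnot(is.numeric(budget), length(budget) == 1, is.finite(budget))
  mats <- problem_matrices(problem)
  res <- solve_core(mats, budget)
  build_allocation(mats, budget, res, problem)
}

#' Exact enumeration oracle for small allocation problems
#'
#' Independent verification route for [solve_allocation()]: enumerates every
#' basic solution of the LP (each assignment of cells to lower bound, upper
#' bound or basic, paired with each same-size subset of binding constraint
#' rows), solves the resulting square linear systems, filters for
#' feasibility and returns the best objective. Exponential in problem size,
#' hence guarded to at most 3 programs x 2 age groups.
#'
#' @param problem A small [allocation_problem()].
#' @param budget Budget in euro.
#' @return A list with `objective`, the optimizing participant vector `x`
#'   (in the canonical cell order of `problem$cells`), and `feasible`.
#' @export
oracle_solve <- function(problem, budget) {
  if (nrow(problem$programs) > 3 || nrow(problem$age_groups) > 2) {
    stop("oracle_solve is guarded to at most 3 programs x 2 age groups",
         call. = FALSE)
  }
  mats <- problem_matrices(problem)
  A <- rbind(mats$cost, mats$A_cap)
  rhs <- c(budget, mats$cap_rhs)
  n <- length(mats$q)
  m <- nrow(A)
  u <- mats$demand
  rtol <- 1e-7 * pmax(1, abs(rhs))
  btol <- 1e-9 * pmax(1, ifelse(is.finite(u), u, 1))

  best_obj <- -Inf
  best_x <- NULL
  status_grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  for (si in seq_len(nrow(status_grid))) {
    st <- status_grid[si, ]
    if (any(st == 1 & !is.finite(u))) next
    basic <- which(st == 2)
    k <- length(basic)
    if (k > m) next
    x0 <- numeric(n)
    x0[st == 1] <- u[st == 1]
    row_sets <- if (k == 0) list(integer(0)) else
      utils::combn(m, k, simplify = FALSE)
    for (rows in row_sets) {
      x <- x0
      if (k > 0) {
        M <- A[rows, basic, drop = FALSE]
        rhs_k <- rhs[rows] - as.vector(A[rows, -basic, drop = FALSE] %*% x0[-basic])
        xb <- tryCatch(solve(M, rhs_k), error = function(e) NULL)
        if (is.null(xb) || any(!is.finite(xb))) next
        x[basic] <- xb
      }
      if (any(x < -btol) || any(x > u + btol)) next
      if (any(as.vector(A %*% x) > rhs + rtol)) next
      obj <- sum(mats$q * x)
      if (obj > best_obj + 1e-12) {
        best_obj <- obj
        best_x <- pmin(pmax(x, 0), u)
      }
    }
  }
  if (is.null(best_x)) {
    return(list(objective = NA_real_, x = NULL, feasible = FALSE))
  }
  list(objective = best_obj, x = best_x, feasible = TRUE)
}

#' Greedy solver for capacity-free problems
#'
#' Without capacity constraints the allocation LP is a continuous knapsack
#' with box constraints: funding cells in ascending order of average cost per
#' QALY up to their demand, funding the marginal cell fractionally, is
#' provably optimal. Ties are broken by (program code, age) lexicographic
#' order.
#'
#' @param problem An [allocation_problem()] with all capacities unbounded and
#'   strictly positive per-cell QALYs and costs.
#' @param budget Budget in euro.
#' @return An `allocation` object.
#' @export
greedy_solve <- function(problem, budget) {
  mats <- problem_matrices(problem)
  if (!is.null(mats$A_cap)) {
    stop("greedy_solve requires all capacities unbounded; ",
         "use solve_allocation for capacitated problems", call. = FALSE)
  }
  if (any(mats$q <= 0) || any(mats$cost <= 0)) {
    stop("greedy_solve requires q > 0 and c > 0 in every cell; ",
         "use solve_allocation otherwise", call. = FALSE)
  }
  stopifnot(budget >= 0)
  cl <- mats$cells
  ratio <- mats$cost / mats$q
  ord <- order(ratio, cl$code, cl$age_id, method = "radix")

  p <- numeric(length(mats$q))
  left <- budget
  marginal_ratio <- 0
  for (i in ord) {
    full_cost <- mats$cost[i] * mats$demand[i]
    if (full_cost <= left) {
      p[i] <- mats$demand[i]
      left <- left - full_cost
    } else {
      p[i] <- left / mats$cost[i]
      left <- 0
      marginal_ratio <- ratio[i]
      break
    }
  }
  res <- list(status = "optimal", x = p,
              objective = sum(p * mats$q),
              duals = c(if (left <= 0 && marginal_ratio > 0) 1 / marginal_ratio else 0,
                        numeric(0)),
              reduced = mats$q - (if (left <= 0 && marginal_ratio > 0)
                1 / marginal_ratio else 0) * mats$cost,
              degenerate = FALSE,
              budget_dual = if (left <= 0 && marginal_ratio > 0) 1 / marginal_ratio else 0)
  build_allocation(mats, budget, res, problem)
}

#' Shadow prices of the constraints at the optimum
#'
#' Dual values of the allocation LP: the budget price is the marginal QALY
#' gain per extra euro of budget (the local slope of the efficiency
#' frontier), capacity prices are marginal QALYs per extra unit of program
#' capacity, and demand prices are marginal QALYs per extra eligible person
#' in a cell. At a degenerate optimum duals need not be unique; the report
#' then carries a degeneracy flag rather than a resolved value.
#'
#' @param problem A validated [allocation_problem()].
#' @param budget Budget in euro.
#' @return A list of class `shadow_price_report` with `budget_price`
#'   (QALY/euro), `capacity` (tibble of QALY/person per program), `demand`
#'   (tibble of QALY/person per cell) and `degenerate`.
#' @export
shadow_prices <- function(problem, budget) {
  alloc <- solve_allocation(problem, budget)
  if (alloc$status != "optimal") {
    stop("shadow prices require an optimal allocation; solver status: ",
         alloc$status, call. = FALSE)
  }
  structure(list(budget_price = alloc$duals$budget,
                 capacity = alloc$duals$capacity,
                 demand = alloc$duals$demand,
                 degenerate = alloc$degenerate),
            class = "shadow_price_report")
}

#' @export
print.shadow_price_report <- function(x, ...) {
  cat("<shadow_price_report>\n")
  cat("  budget price: ", signif(x$budget_price, 6), " QALY per euro\n", sep = "")
  act <- x$capacity[x$capacity$price > 0, ]
  if (nrow(act)) {
    cat("  binding capacities:\n")
    for (i in seq_len(nrow(act))) {
      cat("    ", act$code[i], ": ", signif(act$price[i], 6), " QALY per person\n",
          sep = "")
    }
  }
  if (x$degenerate) cat("  warning: degenerate optimum, duals may be non-unique\n")
  invisible(x)
}

#' Full implementation: maximal health at minimal spend
#'
#' The right endpoint of the efficiency frontier. Lexicographic solve:
#' first maximize total QALYs with the budget constraint removed (bounded by
#' demand and capacity only), then minimize spend among QALY-optimal
#' allocations. Dominated cells (no positive QALY gain) are never funded.
#'
#' @param problem A validated [allocation_problem()].
#' @return An `allocation` whose `spend` is the maximal useful budget and
#'   whose `total_qalys` is the maximal attainable health.
#' @export
max_health_min_cost <- function(problem) {
  viol <- validate_problem(problem)
  if (length(viol) > 0) {
    stop("invalid problem:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  mats <- problem_matrices(problem)
  if (any(mats$q > 0 & !is.finite(mats$demand))) {
    stop("maximal health is unbounded: positive-QALY cell with infinite demand",
         call. = FALSE)
  }
  # stage 1: maximal QALYs ignoring the budget
  res1 <- lp_box_simplex(mats$q, mats$A_cap, mats$cap_rhs, mats$demand)
  if (res1$status != "optimal") {
    stop("stage-1 solver status: ", res1$status, call. = FALSE)
  }
  q_star <- res1$objective
  # stage 2: minimal spend among QALY-optimal allocations; the exact QALY
  # floor is numerically feasible because phase 1 tolerates residual
  # infeasibility well below the solver's feasibility tolerance
  A2 <- rbind(-mats$q, mats$A_cap)
  rhs2 <- c(-q_star, mats$cap_rhs)
  res2 <- lp_box_simplex(-mats$cost, A2, rhs2, mats$demand)
  if (res2$status != "optimal") {
    stop("stage-2 solver status: ", res2$status, call. = FALSE)
  }
  x <- pmin(pmax(res2$x, 0), mats$demand)
  spend <- sum(x * mats$cost)
  res <- list(status = "optimal", x = x, objective = sum(x * mats$q),
              duals = c(0, rep(0, length(mats$cap_rhs))), reduced = rep(0, length(x)),
              degenerate = res2$degenerate, budget_dual = 0)
  alloc <- build_allocation(mats, spend, res, problem)
  alloc$binding <- setdiff(alloc$binding, "budget")
  alloc
}
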