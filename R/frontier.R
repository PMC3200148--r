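# The efficiency frontier: the optimal value of the allocation LP as a
# function of the budget right-hand side. By LP theory this value function is
# concave and piecewise linear; its slopes are the budget shadow prices
# (QALYs per euro), their reciprocals the segment incremental
# cost-effectiveness ratios, and its corner points mark changes in the
# optimal intervention set. Breakpoints are located by bisection on the
# budget dual, which is non-increasing in the budget and changes value
# exactly at the corners.

#' Trace the budget-to-health efficiency frontier
#'
#' Locates all breakpoints of the LP value function between budget 0 and the
#' full-implementation endpoint ([max_health_min_cost()]) by recursive
#' bisection on the budget shadow price, refined to relative width `tol`.
#' Each segment is annotated with its slope (QALY/euro), incremental
#' cost-effectiveness ratio (euro/QALY), and the cells entering and leaving
#' the funded set at its lower end (funded means more than `1e-7`
#' participants, compared at segment midpoints).
#'
#' @param problem A validated [allocation_problem()].
#' @param tol Relative breakpoint width (default 1e-9 of the endpoint budget).
#' @return An object of class `frontier`: a tibble of `segments` (`b_lo`,
#'   `b_hi`, `q_lo`, `q_hi`, `slope`, `icer`, `entering`, `leaving` as list
#'   columns) plus the `endpoint` (maximal useful budget and maximal health)
#'   and the budget-0 baseline.
#' @export
trace_frontier <- function(problem, tol = 1e-9) {
  viol <- validate_problem(problem)
  if (length(viol) > 0) {
    stop("invalid problem:\n  ", paste(viol, collapse = "\n  "), call. = FALSE)
  }
  mats <- problem_matrices(problem)
  end <- max_health_min_cost(problem)
  B <- end$spend

  solve_at <- function(b) solve_core(mats, b)
  base <- solve_at(0)
  if (B <= 1e-9 * max(1, abs(B))) {
    out <- structure(list(
      segments = tibble(b_lo = numeric(0), b_hi = numeric(0),
                        q_lo = numeric(0), q_hi = numeric(0),
                        slope = numeric(0), icer = numeric(0),
                        entering = list(), leaving = list()),
      endpoint = list(budget = B, qalys = end$total_qalys),
      baseline = list(qalys = base$objective,
                      funded = funded_set(mats, base$x))),
      class = "frontier")
    return(out)
  }

  tol_abs <- max(tol * B, B * 1e-12, .Machine$double.eps)
  dual_close <- function(a, b) {
    abs(a - b) <= 1e-7 * max(abs(a), abs(b), .Machine$double.xmin)
  }

  find_breaks <- function(lo, dlo, hi, dhi) {
    if (dual_close(dlo, dhi)) return(numeric(0))
    if (hi - lo <= tol_abs) return((lo + hi) / 2)
    mid <- (lo + hi) / 2
    dmid <- solve_at(mid)$budget_dual
    c(find_breaks(lo, dlo, mid, dmid), find_breaks(mid, dmid, hi, dhi))
  }

  d0 <- solve_at(0)$budget_dual
  dB <- solve_at(B)$budget_dual
  interior <- find_breaks(0, d0, B, dB)
  interior <- interior[interior > tol_abs & interior < B - tol_abs]
  bps <- c(0, sort(interior), B)
  # merge breakpoints closer than the refinement width
  keep <- c(TRUE, diff(bps) > 2 * tol_abs)
  bps <- bps[keep]
  if (bps[length(bps)] != B) bps[length(bps)] <- B

  K <- length(bps) - 1
  sol_bp <- lapply(bps, solve_at)
  q_bp <- vapply(sol_bp, function(s) s$objective, numeric(1))
  prev_funded <- funded_set(mats, base$x)
  seg_rows <- vector("list", K)
  for (i in seq_len(K)) {
    mid <- (bps[i] + bps[i + 1]) / 2
    sm <- solve_at(mid)
    fset <- funded_set(mats, sm$x)
    slope <- sm$budget_dual
    seg_rows[[i]] <- tibble(
      b_lo = bps[i], b_hi = bps[i + 1],
      q_lo = q_bp[i], q_hi = q_bp[i + 1],
      slope = slope, icer = 1 / slope,
      entering = list(setdiff(fset, prev_funded)),
      leaving = list(setdiff(prev_funded, fset))
    )
    prev_funded <- fset
  }
  segments <- dplyr::bind_rows(seg_rows)
  # drop zero-width artifacts and merge adjacent segments with equal slope
  segments <- segments[segments$b_hi - segments$b_lo > tol_abs / 2, ]
  if (nrow(segments) > 1) {
    same <- c(FALSE, abs(diff(segments$slope)) <=
                1e-7 * pmax(segments$slope[-1], 1e-12))
    if (any(same)) {
      keep_idx <- which(!same)
      merged <- vector("list", length(keep_idx))
      for (g in seq_along(keep_idx)) {
        i0 <- keep_idx[g]
        i1 <- if (g < length(keep_idx)) keep_idx[g + 1] - 1 else nrow(segments)
        row <- segments[i0, ]
        row$b_hi <- segments$b_hi[i1]
        row$q_hi <- segments$q_hi[i1]
        merged[[g]] <- row
      }
      segments <- dplyr::bind_rows(merged)
    }
  }

  structure(list(segments = segments,
                 endpoint = list(budget = B, qalys = end$total_qalys),
                 baseline = list(qalys = base$objective,
                                 funded = funded_set(mats, base$x))),
            class = "frontier")
}

funded_set <- function(mats, x) {
  if (is.null(x)) return(character(0))
  mats$cells$short_name[x > 1e-7]
}

#' @export
print.frontier <- function(x, ...) {
  cat("<frontier> ", nrow(x$segments), " segments, endpoint (",
      format(round(x$endpoint$budget), big.mark = ","), " euro, ",
      format(round(x$endpoint$qalys, 1), big.mark = ","), " QALYs)\n", sep = "")
  if (nrow(x$segments) > 0) {
    cat("  segment ICERs (euro/QALY): ",
        paste(format(round(x$segments$icer)), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate the frontier value function at given budgets
#'
#' Piecewise-linear interpolation of maximal attainable QALYs; budgets beyond
#' the endpoint saturate at the endpoint's health level.
#'
#' @param frontier A [trace_frontier()] result.
#' @param budget Vector of budgets (euro).
#' @return Maximal QALYs attainable at each budget.
#' @export
frontier_value <- function(frontier, budget) {
  stopifnot(inherits(frontier, "frontier"))
  seg <- frontier$segments
  vapply(budget, function(b) {
    if (nrow(seg) == 0 || b >= frontier$endpoint$budget) {
      return(frontier$endpoint$qalys)
    }
    if (b <= 0) return(frontier$baseline$qalys)
    i <- max(which(seg$b_lo < b))
    seg$q_lo[i] + seg$slope[i] * (b - seg$b_lo[i])
  }, numeric(1))
}

frontier_icer_at <- function(frontier, budget) {
  seg <- frontier$segments
  if (nrow(seg) == 0 || budget > frontier$endpoint$budget) return(NA_real_)
  if (budget <= 0) return(seg$icer[1])
  # a budget exactly at a breakpoint belongs to the left segment
  i <- max(which(seg$b_lo < budget))
  seg$icer[i]
}

#' Summarize the optimal allocation at one budget
#'
#' Reports the quantities of the study's budget tables: spend and health
#' gained, the percentage of each accruing to general-population programs,
#' the incremental cost per QALY of the frontier segment containing the
#' budget, and the intervention cells entering/leaving the optimal set
#' relative to a reference budget (formatted with `+`/`-` prefixes).
#'
#' @param problem A validated [allocation_problem()].
#' @param budget Budget in euro.
#' @param frontier Optional [trace_frontier()] result; when supplied, the
#'   ICER is read from the segment containing the budget, otherwise from the
#'   budget shadow price at the solve. Budgets beyond the frontier endpoint
#'   are reported at the endpoint with `saturated = TRUE`.
#' @param reference_budget Optional smaller budget against which
#'   entering/leaving cells are computed.
#' @return A one-row tibble with columns `budget`, `spend`, `total_qalys`,
#'   `pct_spend_general`, `pct_qaly_general`, `icer`, `changes`, `entering`,
#'   `leaving` (list columns), `saturated` and `undefined` (percentages
#'   undefined at zero spend).
#' @export
summarize_allocation <- function(problem, budget, frontier = NULL,
                                 reference_budget = NULL) {
  stopifnot(budget >= 0)
  alloc <- solve_allocation(problem, budget)
  if (alloc$status != "optimal") {
    stop("solver status: ", alloc$status, call. = FALSE)
  }
  pt <- alloc$participants
  spend <- alloc$spend
  qalys <- alloc$total_qalys
  saturated <- if (!is.null(frontier)) {
    budget > frontier$endpoint$budget * (1 + 1e-12)
  } else {
    spend < budget - 1e-7 * max(1, budget)
  }
  undefined <- spend <= 0 || qalys <= 0
  gen <- pt$population == "general"
  pct_spend <- if (spend > 0) 100 * sum(pt$spend[gen]) / spend else NA_real_
  pct_qaly <- if (qalys > 0) 100 * sum(pt$qalys[gen]) / qalys else NA_real_

  icer <- if (!is.null(frontier)) {
    frontier_icer_at(frontier, min(budget, frontier$endpoint$budget))
  } else if (alloc$duals$budget > 0) {
    1 / alloc$duals$budget
  } else {
    NA_real_
  }

  entering <- character(0)
  leaving <- character(0)
  if (!is.null(reference_budget)) {
    ref <- solve_allocation(problem, reference_budget)
    f_ref <- ref$participants$short_name[ref$participants$participants > 1e-7]
    f_now <- pt$short_name[pt$participants > 1e-7]
    entering <- setdiff(f_now, f_ref)
    leaving <- setdiff(f_ref, f_now)
  }
  tibble(
    budget = budget, spend = spend, total_qalys = qalys,
    pct_spend_general = pct_spend, pct_qaly_general = pct_qaly,
    icer = icer, changes = format_changes(entering, leaving),
    entering = list(entering), leaving = list(leaving),
    saturated = saturated, undefined = undefined
  )
}

format_changes <- function(entering, leaving) {
  parts <- character(0)
  if (length(entering) > 0) parts <- c(parts, paste("+", paste(entering, collapse = ", ")))
  if (length(leaving) > 0) parts <- c(parts, paste("-", paste(leaving, collapse = ", ")))
  if (length(parts) == 0) "NA" else paste(parts, collapse = " ")
}

#' Average cost-effectiveness of full implementation
#'
#' The frontier's right endpoint divided out: total spend over total QALYs at
#' full implementation, i.e. the average price of one QALY when every
#' worthwhile intervention is funded to its demand and capacity limits.
#'
#' @param problem A validated [allocation_problem()].
#' @return A list with `raw` (euro/QALY), `rounded` (nearest 100 euro),
#'   `spend` and `qalys`.
#' @export
average_cer_of_endpoint <- function(problem) {
  end <- max_health_min_cost(problem)
  if (!is.finite(end$total_qalys) || end$total_qalys <= 0) {
    stop("endpoint has no positive QALY gain; average CER undefined",
         call. = FALSE)
  }
  raw <- end$spend / end$total_qalys
  list(raw = raw, rounded = round_to_hundred(raw),
       spend = end$spend, qalys = end$total_qalys)
}
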