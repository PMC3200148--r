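# Internal dense two-phase primal simplex for box-constrained LPs:
#
#   maximize  obj'x   subject to   A x <= rhs,   0 <= x <= upper.
#
# The allocation LPs solved here are small (tens of variables, a budget row
# plus one capacity row per program), so the basis is refactorized with
# solve() at every iteration rather than updated; this trades speed for
# numerical robustness and implementation transparency. Rows are scaled by
# their largest coefficient before solving; duals are returned on the
# original scale. Deterministic: Dantzig pricing with smallest-index
# tie-breaks, switching to Bland's rule after a stall to preclude cycling.

lp_box_simplex <- function(obj, A, rhs, upper, tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  m <- if (is.null(A)) 0L else nrow(A)
  stopifnot(length(upper) == n, m == 0 || ncol(A) == n, length(rhs) == m)

  if (m == 0L) {
    if (any(obj > tol & !is.finite(upper))) {
      stop("LP is unbounded (positive objective on an unbounded variable)",
           call. = FALSE)
    }
    x <- ifelse(obj > tol, upper, 0)
    return(list(status = "optimal", x = x, objective = sum(obj * x),
                duals = numeric(0), reduced = obj, degenerate = FALSE))
  }

  row_scale <- pmax(apply(abs(A), 1, max), 1e-12)
  As <- A / row_scale
  bs <- rhs / row_scale

  Afull <- cbind(As, diag(m))
  U <- c(upper, rep(Inf, m))
  neg <- which(bs < -tol)
  n_art <- length(neg)
  if (n_art > 0) {
    Aart <- matrix(0, m, n_art)
    Aart[cbind(neg, seq_len(n_art))] <- -1
    Afull <- cbind(Afull, Aart)
    U <- c(U, rep(Inf, n_art))
  }
  N <- ncol(Afull)

  basis <- n + seq_len(m)
  if (n_art > 0) basis[neg] <- n + m + seq_len(n_art)
  at_upper <- rep(FALSE, N)

  if (n_art > 0) {
    obj1 <- rep(0, N)
    obj1[n + m + seq_len(n_art)] <- -1
    res1 <- simplex_core(Afull, bs, U, obj1, basis, at_upper, tol, max_iter)
    if (res1$status != "optimal") {
      stop("LP solver failure in phase 1: ", res1$status, call. = FALSE)
    }
    if (res1$objective < -1e-7) {
      return(list(status = "infeasible", x = NULL, objective = NA_real_,
                  duals = NULL, reduced = NULL, degenerate = FALSE))
    }
    basis <- res1$basis
    at_upper <- res1$at_upper
    U[n + m + seq_len(n_art)] <- 0
    at_upper[n + m + seq_len(n_art)] <- FALSE
  }

  obj2 <- c(obj, rep(0, N - n))
  res <- simplex_core(Afull, bs, U, obj2, basis, at_upper, tol, max_iter)
  if (res$status != "optimal") {
    stop("LP solver failure: ", res$status, call. = FALSE)
  }

  x <- res$x[seq_len(n)]
  y <- res$y / row_scale
  reduced <- obj - as.vector(crossprod(A, y))
  list(status = "optimal", x = x, objective = sum(obj * x), duals = y,
       reduced = reduced, degenerate = res$degenerate)
}

simplex_core <- function(Af, b, U, obj, basis, at_upper, tol, max_iter) {
  N <- ncol(Af)
  m <- nrow(Af)
  bland <- FALSE
  stall <- 0L
  last_obj <- -Inf

  for (iter in seq_len(max_iter)) {
    B <- Af[, basis, drop = FALSE]
    nb <- setdiff(seq_len(N), basis)
    x <- numeric(N)
    up_nb <- nb[at_upper[nb]]
    x[up_nb] <- U[up_nb]
    rhs_eff <- b
    if (length(up_nb) > 0) {
      rhs_eff <- b - as.vector(Af[, up_nb, drop = FALSE] %*% x[up_nb])
    }
    xB <- tryCatch(solve(B, rhs_eff),
                   error = function(e) stop("LP solver failure: singular basis",
                                            call. = FALSE))
    x[basis] <- xB
    y <- solve(t(B), obj[basis])
    d <- obj - as.vector(crossprod(Af, y))

    cand_lo <- nb[!at_upper[nb] & d[nb] > tol]
    cand_hi <- nb[at_upper[nb] & d[nb] < -tol]
    cand <- c(cand_lo, cand_hi)
    if (length(cand) == 0) {
      degen <- any(abs(xB) < tol * 10) ||
        any(is.finite(U[basis]) & abs(U[basis] - xB) < tol * 10)
      return(list(status = "optimal", x = x, y = y, basis = basis,
                  at_upper = at_upper, objective = sum(obj * x),
                  degenerate = degen))
    }

    if (bland) {
      e <- min(cand)
    } else {
      score <- abs(d[cand])
      e <- cand[which.max(score)]
    }
    from_upper <- at_upper[e]
    dirn <- if (from_upper) -1 else 1
    w <- solve(B, Af[, e])
    dw <- dirn * w

    # step limits: basic variables hitting their bounds, then the entering
    # variable reaching its opposite bound
    t_best <- if (is.finite(U[e])) U[e] else Inf
    r_best <- 0L
    hit_upper <- FALSE
    for (i in seq_len(m)) {
      if (dw[i] > tol) {
        ti <- xB[i] / dw[i]
        if (ti < t_best - 1e-12) { t_best <- ti; r_best <- i; hit_upper <- FALSE }
      } else if (dw[i] < -tol && is.finite(U[basis[i]])) {
        ti <- (U[basis[i]] - xB[i]) / (-dw[i])
        if (ti < t_best - 1e-12) { t_best <- ti; r_best <- i; hit_upper <- TRUE }
      }
    }
    if (!is.finite(t_best)) {
      return(list(status = "unbounded", x = NULL, y = NULL, basis = basis,
                  at_upper = at_upper, objective = Inf, degenerate = FALSE))
    }
    t_best <- max(t_best, 0)

    if (r_best == 0L) {
      # entering variable swaps bound; basis unchanged
      at_upper[e] <- !from_upper
    } else {
      lv <- basis[r_best]
      at_upper[lv] <- hit_upper
      basis[r_best] <- e
      at_upper[e] <- FALSE
    }

    if (t_best < tol) stall <- stall + 1L else stall <- 0L
    if (stall > 50L) bland <- TRUE
  }
  list(status = "iteration limit reached", x = NULL, y = NULL, basis = basis,
       at_upper = at_upper, objective = NA_real_, degenerate = FALSE)
}
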