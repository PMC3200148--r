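# Small problem builders used across the test files.

# build an allocation problem from bare vectors; q, c, dem are laid out
# program-major (all ages of program 1, then program 2, ...)
mk_problem <- function(q, cost, dem, cap, codes = NULL, populations = NULL) {
  np <- length(cap)
  na <- length(q) / np
  stopifnot(na == round(na))
  if (is.null(codes)) codes <- sprintf("P%02d", seq_len(np))
  if (is.null(populations)) populations <- rep("general", np)
  cells <- tibble::tibble(
    program_code = rep(codes, each = na),
    program_title = rep(codes, each = na),
    population = rep(populations, each = na),
    age_label = rep(paste0("a", seq_len(na)), np),
    qaly_per_participant = q,
    cost_per_participant = cost,
    demand = dem,
    capacity = rep(cap, each = na)
  )
  allocation_problem(cells)
}

# random small instance for oracle-equivalence checks (<= 3 programs x 2 ages)
random_small_problem <- function(allow_cost_saving = TRUE) {
  np <- sample(1:3, 1)
  na <- sample(1:2, 1)
  n <- np * na
  q <- stats::runif(n, 0.1, 2)
  cost <- stats::runif(n, 10, 500)
  if (allow_cost_saving && stats::runif(1) < 0.2) {
    cost[sample(n, 1)] <- -stats::runif(1, 10, 100)
  }
  dem <- stats::runif(n, 1, 20)
  cap <- ifelse(stats::runif(np) < 0.5, stats::runif(np, 5, 25), Inf)
  list(problem = mk_problem(q, cost, dem, cap),
       budget = stats::runif(1, 0, 1.2 * sum(pmax(cost, 0) * dem)))
}

# random capacity-free instance with strictly positive q and c
random_free_problem <- function(np = 4, na = 3) {
  n <- np * na
  q <- stats::runif(n, 0.05, 2)
  cost <- stats::runif(n, 20, 5000)
  dem <- stats::runif(n, 10, 5000)
  list(problem = mk_problem(q, cost, dem, rep(Inf, np)),
       budget = stats::runif(1, 0, 1.1 * sum(cost * dem)))
}

# the two-ratio construction used in several frontier checks:
# cell A at 100 euro/QALY with a 500-euro full spend, cell B at 200 euro/QALY
# with a 400-euro full spend
two_ratio_problem <- function() {
  mk_problem(q = c(1, 0.5), cost = c(100, 100), dem = c(5, 4),
             cap = c(Inf, Inf), codes = c("A", "B"))
}

# two-state survival model (well -> dead at constant probability 1 - s) with
# utility 1: discounted life expectancy has a geometric closed form
two_state_model <- function(s) {
  cohort_model(
    transition = function(age) matrix(c(s, 0, 1 - s,
                                        0, 0, 1,
                                        0, 0, 1), 3, 3, byrow = TRUE),
    utility = function(age) c(1, 0, 0),
    care_cost = function(age) c(0, 0, 0),
    age_cap = Inf
  )
}
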