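#' Discounting specification
#'
#' Differential discounting of health and costs, with health at 1.5% and
#' costs at 4% annually as the default (the Dutch pharmacoeconomic guideline
#' convention), and a time horizon in years or `"lifetime"`.
#'
#' @param rate_health,rate_cost Annual discount rates (fractions, >= 0).
#' @param horizon Positive number of years, or `"lifetime"` to follow the
#'   cohort until extinction.
#' @return A `discount_spec` object.
#' @export
discount_spec <- function(rate_health = 0.015, rate_cost = 0.04,
                          horizon = "lifetime") {
  stopifnot(is.numeric(rate_health), rate_health >= 0,
            is.numeric(rate_cost), rate_cost >= 0)
  if (!(identical(horizon, "lifetime") || (is.numeric(horizon) && horizon > 0))) {
    stop("horizon must be a positive number of years or \"lifetime\"",
         call. = FALSE)
  }
  structure(list(rate_health = rate_health, rate_cost = rate_cost,
                 horizon = horizon),
            class = "discount_spec")
}

#' Net present value of an annual stream
#'
#' Discounts a stream of per-year amounts: the amount for year `t` is divided
#' by `(1 + rate)^t`, so year-0 amounts are undiscounted. Truncation of the
#' stream excludes later years entirely.
#'
#' @param stream Amounts for consecutive years.
#' @param rate Annual discount rate (fraction, >= 0).
#' @param first_year Year index of the first element (default 1, i.e. the
#'   first amount falls at the end of year one).
#' @return The net present value; 0 for an empty stream.
#' @export
#' @examples
#' npv(rep(1, 10), 0)      # 10
#' npv(1, 0.04)            # 1/1.04
npv <- function(stream, rate, first_year = 1) {
  stopifnot(is.numeric(rate), length(rate) == 1, rate >= 0)
  if (length(stream) == 0) return(0)
  if (any(!is.finite(stream))) stop("stream must be finite", call. = FALSE)
  t <- first_year + seq_along(stream) - 1
  sum(stream / (1 + rate)^t)
}

#' Multi-state annual-cycle cohort model
#'
#' A deliberately simplified stand-in for a full chronic-disease
#' microsimulation: three states (`well`, `chronic`, `dead`), age-dependent
#' annual transition probabilities, age-dependent QALY weights per state and
#' annual healthcare costs per state. It exists to produce per-participant
#' lifetime-discounted QALY and cost differences versus usual care with the
#' qualitative structure of cardiovascular/diabetes prevention: health gains
#' that accrue late in life, care costs that continue in life-years gained,
#' and quality of life that declines with advancing age.
#'
#' @param transition `function(age)` returning a 3x3 row-stochastic matrix in
#'   state order (well, chronic, dead); the dead state must be absorbing.
#' @param utility `function(age)` returning QALY weights in `[0, 1]` for the
#'   three states (dead must be 0); weights must not increase with age.
#' @param care_cost `function(age)` returning non-negative annual healthcare
#'   costs (euro) for the three states (dead must be 0).
#' @param age_cap Hard upper age for the lifetime horizon (default 105; may
#'   be `Inf`, in which case the simulation stops once the cohort is
#'   numerically extinct).
#' @return A `cohort_model` object.
#' @export
cohort_model <- function(transition, utility, care_cost, age_cap = 105) {
  stopifnot(is.function(transition), is.function(utility), is.function(care_cost))
  m <- structure(list(states = c("well", "chronic", "dead"),
                      transition = transition, utility = utility,
                      care_cost = care_cost, age_cap = age_cap),
                 class = "cohort_model")
  check_transition(m, 50)  # fail fast on an obviously broken model
  m
}

check_transition <- function(model, age, tol = 1e-10) {
  P <- model$transition(age)
  if (!is.matrix(P) || any(dim(P) != c(3, 3)) || any(!is.finite(P))) {
    stop("transition(", age, ") must return a finite 3x3 matrix", call. = FALSE)
  }
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop("transition probabilities at age ", age, " outside [0, 1]", call. = FALSE)
  }
  if (any(abs(rowSums(P) - 1) > tol)) {
    stop("transition matrix rows at age ", age, " do not sum to 1 ",
         "(non-stochastic matrix)", call. = FALSE)
  }
  if (any(abs(P[3, ] - c(0, 0, 1)) > tol)) {
    stop("dead state not absorbing at age ", age, call. = FALSE)
  }
  invisible(P)
}

#' Intervention effect on the cohort model
#'
#' An intervention acts as a hazard multiplier on the well-to-chronic and/or
#' well-to-dead transitions for a limited number of years (after which the
#' multiplier reverts to 1, encoding relapse and non-adherence), and charges
#' an annual cost for a limited number of years.
#'
#' @param multiplier_chronic,multiplier_death Hazard multipliers (> 0) on the
#'   well-to-chronic and well-to-dead transitions; 1 means no effect.
#' @param effect_duration Years the multipliers apply (>= 0).
#' @param annual_cost Annual intervention cost per (living) participant, euro.
#' @param cost_duration Years the cost is charged (>= 0).
#' @return An `intervention_effect` object.
#' @export
intervention_effect <- function(multiplier_chronic = 1, multiplier_death = 1,
                                effect_duration = 0, annual_cost = 0,
                                cost_duration = 0) {
  stopifnot(multiplier_chronic > 0, multiplier_death > 0,
            effect_duration >= 0, cost_duration >= 0)
  structure(list(multiplier_chronic = multiplier_chronic,
                 multiplier_death = multiplier_death,
                 effect_duration = effect_duration,
                 annual_cost = annual_cost,
                 cost_duration = cost_duration),
            class = "intervention_effect")
}

apply_hazard_multiplier <- function(P, effect) {
  # multiplier on the hazard scale: p' = 1 - (1 - p)^m; a multiplier of
  # exactly 1 must leave the matrix bit-identical (null-effect identity)
  if (effect$multiplier_chronic == 1 && effect$multiplier_death == 1) return(P)
  pc <- if (effect$multiplier_chronic == 1) P[1, 2] else
    1 - (1 - P[1, 2])^effect$multiplier_chronic
  pd <- if (effect$multiplier_death == 1) P[1, 3] else
    1 - (1 - P[1, 3])^effect$multiplier_death
  pw <- 1 - pc - pd
  if (pw < 0) {
    stop("hazard multipliers push well-state exit probability above 1",
         call. = FALSE)
  }
  P[1, ] <- c(pw, pc, pd)
  P
}

#' Simulate a cohort and accumulate discounted QALYs and costs
#'
#' Deterministic (expected-value) cohort simulation with annual cycles. The
#' cohort starts in the well state at `start_age` and is followed until
#' dead-state occupancy reaches 1 - 1e-9, the model's age cap, or the
#' discount horizon, whichever comes first. QALYs and care costs for cycle
#' `k` (year `k`) are discounted by `(1 + rate)^-k`; with `half_cycle = TRUE`
#' (the default) the cycle's reward is the average of start- and end-of-cycle
#' occupancy-weighted values (trapezoid rule), otherwise end-of-cycle
#' occupancy is used. Intervention costs are charged at cycle start (year
#' `k - 1`, so the first year's cost is undiscounted) in proportion to the
#' living share of the cohort.
#'
#' @param model A [cohort_model()].
#' @param effect An [intervention_effect()] or `NULL` for usual care.
#' @param start_age Cohort entry age in years.
#' @param discount A [discount_spec()].
#' @param half_cycle Use the half-cycle (trapezoid) correction for QALYs and
#'   care costs.
#' @param initial Initial occupancy over (well, chronic, dead); defaults to
#'   everyone well.
#' @return A list with discounted `qalys`, total `costs` (care plus
#'   intervention), `care_costs`, `intervention_costs`, the number of cycles
#'   run, and the final occupancy vector.
#' @export
simulate_cohort <- function(model, effect = NULL, start_age,
                            discount = discount_spec(), half_cycle = TRUE,
                            initial = c(1, 0, 0)) {
  stopifnot(inherits(model, "cohort_model"),
            inherits(discount, "discount_spec"),
            length(initial) == 3, all(initial >= 0),
            abs(sum(initial) - 1) < 1e-9)
  if (!is.null(effect)) stopifnot(inherits(effect, "intervention_effect"))
  if (start_age >= model$age_cap) {
    stop("start_age must lie below the model's age cap", call. = FALSE)
  }
  horizon <- if (identical(discount$horizon, "lifetime")) Inf else discount$horizon
  rh <- discount$rate_health
  rc <- discount$rate_cost

  occ <- initial
  age <- start_age
  k <- 0L
  qalys <- 0
  care <- 0
  interv <- 0
  u_now <- model$utility(age)
  c_now <- model$care_cost(age)
  if (any(u_now < 0) || any(u_now > 1) || u_now[3] != 0) {
    stop("utilities must lie in [0, 1] with 0 for the dead state", call. = FALSE)
  }
  if (any(c_now < 0) || c_now[3] != 0) {
    stop("care costs must be non-negative with 0 for the dead state",
         call. = FALSE)
  }

  while (occ[3] < 1 - 1e-9 && age < model$age_cap && k < horizon) {
    P <- check_transition(model, age)
    if (!is.null(effect) && k < effect$effect_duration) {
      P <- apply_hazard_multiplier(P, effect)
    }
    occ_next <- as.vector(occ %*% P)
    u_next <- model$utility(age + 1)
    c_next <- model$care_cost(age + 1)

    v0 <- sum(occ * u_now); v1 <- sum(occ_next * u_next)
    g0 <- sum(occ * c_now); g1 <- sum(occ_next * c_next)
    q_k <- if (half_cycle) (v0 + v1) / 2 else v1
    g_k <- if (half_cycle) (g0 + g1) / 2 else g1
    qalys <- qalys + q_k / (1 + rh)^(k + 1)
    care <- care + g_k / (1 + rc)^(k + 1)

    if (!is.null(effect) && k < effect$cost_duration) {
      alive <- occ[1] + occ[2]
      interv <- interv + effect$annual_cost * alive / (1 + rc)^k
    }

    occ <- occ_next
    age <- age + 1
    k <- k + 1L
    u_now <- u_next
    c_now <- c_next
  }

  list(qalys = qalys, costs = care + interv, care_costs = care,
       intervention_costs = interv, cycles = k, final_occupancy = occ)
}

#' Per-participant net outcomes of one intervention cell
#'
#' Runs the cohort twice (usual care and with the intervention) and returns
#' the net present values the allocation model needs: the QALY gain
#' `q = QALYs(intervention) - QALYs(usual care)` and the net cost
#' `c = intervention costs + care costs(intervention) - care costs(usual
#' care)`, which includes healthcare costs incurred in life-years gained.
#'
#' @inheritParams simulate_cohort
#' @return A list with `qaly`, `cost`, and the two full simulation results
#'   (`treated`, `control`).
#' @export
evaluate_cell <- function(model, effect, start_age,
                          discount = discount_spec(), half_cycle = TRUE) {
  control <- simulate_cohort(model, NULL, start_age, discount, half_cycle)
  treated <- simulate_cohort(model, effect, start_age, discount, half_cycle)
  list(qaly = treated$qalys - control$qalys,
       cost = treated$intervention_costs + treated$care_costs - control$care_costs,
       treated = treated, control = control)
}
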