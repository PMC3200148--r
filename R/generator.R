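# Seeded generator of complete allocation problems with the structure of the
# published study: 12 programs (half for the general population, half for
# diagnosed diabetes patients) by 3 age groups, per-participant outcomes from
# the cohort simulator, demand limits an order of magnitude smaller for the
# diabetes target group, and per-program capacity a fixed fraction of total
# demand. Average cost-per-QALY ratios are calibrated into the published
# league-table range by choosing each cell's intervention cost stream.

#' Default synthetic cohort model for one target population
#'
#' A three-state model with Gompertz-like age-increasing mortality and
#' chronic-disease incidence, age-declining QALY weights and age-increasing
#' annual care costs. The diabetes variant carries higher baseline mortality,
#' incidence, care costs and slightly lower utilities, emulating a diagnosed
#' high-risk group. All parameter values are synthetic stand-ins chosen to
#' give realistic magnitudes (remaining life expectancy around 50, 28 and 14
#' years at ages 32, 55 and 72; utilities declining with age), not estimates
#' for any real population.
#'
#' @param population `"general"` or `"diabetes"`.
#' @return A [cohort_model()].
#' @export
default_cohort_model <- function(population = c("general", "diabetes")) {
  population <- match.arg(population)
  mort_mult <- if (population == "diabetes") 1.8 else 1
  inc_mult <- if (population == "diabetes") 2.5 else 1
  u_shift <- if (population == "diabetes") 0.04 else 0
  cost_shift <- if (population == "diabetes") 1300 else 0

  transition <- function(age) {
    pwd <- min(0.6, mort_mult * 3e-5 * exp(0.085 * age))
    pwc <- min(0.3, inc_mult * 8e-4 * exp(0.045 * age))
    pcd <- min(0.8, 2.2 * pwd + 0.01)
    matrix(c(1 - pwc - pwd, pwc, pwd,
             0, 1 - pcd, pcd,
             0, 0, 1),
           nrow = 3, byrow = TRUE)
  }
  utility <- function(age) {
    c(max(0.55, 0.93 - u_shift - 0.0018 * (age - 20)),
      max(0.35, 0.75 - u_shift - 0.0022 * (age - 20)),
      0)
  }
  care_cost <- function(age) {
    c(900 + cost_shift + 25 * max(0, age - 20),
      3800 + cost_shift + 55 * max(0, age - 20),
      0)
  }
  cohort_model(transition, utility, care_cost, age_cap = 105)
}

default_age_groups <- function(n_ages = 3) {
  if (n_ages == 3) {
    tibble(age_id = 1:3, label = c("20-44", "45-64", "65+"),
           start_age = c(32, 55, 72))
  } else {
    starts <- seq(30, 80, length.out = n_ages)
    tibble(age_id = seq_len(n_ages),
           label = paste0("age", round(starts)),
           start_age = round(starts))
  }
}

#' Generate a seeded cohort configuration
#'
#' Draws, deterministically for a given seed, the full configuration behind a
#' synthetic allocation problem: a cohort model per population, an
#' intervention effect (hazard multipliers, effect duration, cost stream) per
#' program-by-age cell, demand limits and per-program capacities. Cell
#' intervention costs are calibrated so that every cell's lifetime average
#' cost-per-QALY ratio falls at a log-uniformly drawn target inside
#' `cer_range`; effects whose care-cost consequences alone already exceed the
#' upper end of the range are redrawn, and a calibration error is raised
#' after `max_iter` failed redraws.
#'
#' @param seed Integer seed; the configuration is a deterministic function of
#'   it.
#' @param n_programs Number of programs (even; half general population, half
#'   diabetes patients).
#' @param n_ages Number of age groups.
#' @param cer_range Target range (euro/QALY) for average cost-effectiveness
#'   ratios, defaulting to the published league-table extremes.
#' @param capacity_tightness Per-program capacity as a fraction of total
#'   demand, in (0, 1]; 1 means capacity never binds at unlimited budget.
#' @param max_iter Redraw cap per program for CER calibration.
#' @return A `cohort_config` object.
#' @export
generate_config <- function(seed, n_programs = 12, n_ages = 3,
                            cer_range = c(1400, 59600),
                            capacity_tightness = 0.6, max_iter = 25) {
  stopifnot(n_programs %% 2 == 0, n_programs >= 2,
            capacity_tightness > 0, capacity_tightness <= 1,
            length(cer_range) == 2, cer_range[1] > 0,
            cer_range[2] > cer_range[1])
  set.seed(as.integer(seed))
  ages <- default_age_groups(n_ages)
  half <- n_programs / 2
  programs <- tibble(
    program_id = seq_len(n_programs),
    code = c(paste0("G", LETTERS[seq_len(half)]),
             paste0("D", LETTERS[seq_len(half)])),
    title = c(paste("General-population program", LETTERS[seq_len(half)]),
              paste("Diabetes program", LETTERS[seq_len(half)])),
    population = rep(c("general", "diabetes"), each = half)
  )
  models <- list(general = default_cohort_model("general"),
                 diabetes = default_cohort_model("diabetes"))
  discount <- discount_spec()

  # Target average CERs rise with age within a program, as in the published
  # league table (prevention is cheapest where the full effect chain still
  # lies ahead): a program-level base ratio times age multipliers, clipped
  # into cer_range.
  cells <- list()
  for (j in seq_len(n_programs)) {
    pop <- programs$population[j]
    model <- models[[pop]]
    done <- FALSE
    for (try in seq_len(max_iter)) {
      mc <- stats::runif(1, 0.70, 0.95)
      md <- stats::runif(1, 0.85, 0.99)
      eff_dur <- sample(8:25, 1)
      cost_dur <- sample(2:10, 1)
      base_eff <- intervention_effect(mc, md, eff_dur, 0, 0)
      base_t <- exp(stats::runif(1, log(cer_range[1]), log(cer_range[2] / 3)))
      mults <- cumprod(c(1, stats::runif(n_ages - 1, 1.0, 2.2)))
      ok <- TRUE
      rows <- vector("list", n_ages)
      for (a in seq_len(n_ages)) {
        sa <- ages$start_age[a]
        ev <- evaluate_cell(model, base_eff, sa, discount)
        ev50 <- evaluate_cell(model, base_eff, sa,
                              discount_spec(discount$rate_health,
                                            discount$rate_cost, 50))
        ev25 <- evaluate_cell(model, base_eff, sa,
                              discount_spec(discount$rate_health,
                                            discount$rate_cost, 25))
        # cost factor: discounted, survival-weighted years of cost payment
        probe <- intervention_effect(mc, md, eff_dur, 1, cost_dur)
        fac <- simulate_cohort(model, probe, sa, discount)$intervention_costs
        if (ev$qaly <= 0 || ev25$qaly <= 0 || fac <= 0) { ok <- FALSE; break }
        # calibration floor on the intervention cost so that the cell's
        # average CER is non-increasing in the time horizon (truncation must
        # never make a cell look cheaper): for horizon pair (long, short),
        # (i + c_s)/q_s >= (i + c_l)/q_l requires i >= (q_s c_l - q_l c_s) /
        # (q_l - q_s) whenever q_l > q_s
        int_min <- 0
        feasible <- TRUE
        for (pair in list(list(ev, ev50), list(ev50, ev25))) {
          lng <- pair[[1]]; shrt <- pair[[2]]
          dq <- lng$qaly - shrt$qaly
          if (dq > 1e-12) {
            int_min <- max(int_min,
                           (shrt$qaly * lng$cost - lng$qaly * shrt$cost) / dq)
          } else if (lng$cost > shrt$cost + 1e-9) {
            feasible <- FALSE
          }
        }
        if (!feasible) { ok <- FALSE; break }
        floor_t <- max(cer_range[1], ev$cost / ev$qaly,
                       (int_min + ev$cost) / ev$qaly)
        if (floor_t > cer_range[2]) { ok <- FALSE; break }
        target <- min(max(base_t * mults[a], floor_t), cer_range[2])
        annual <- (target * ev$qaly - ev$cost) / fac
        rows[[a]] <- list(age_id = a, target_cer = target,
                          effect = intervention_effect(mc, md, eff_dur,
                                                       annual, cost_dur))
      }
      if (ok) {
        cells[[j]] <- rows
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop("CER calibration failed for program ", programs$code[j],
           " after ", max_iter, " redraws", call. = FALSE)
    }
  }

  # demand: diabetes target groups are an order of magnitude smaller
  demand <- matrix(0, n_programs, n_ages)
  for (j in seq_len(n_programs)) {
    if (programs$population[j] == "general") {
      total <- stats::runif(1, 1.5e5, 6e5)
      shares <- c(0.45, 0.35, 0.20)
    } else {
      total <- stats::runif(1, 1.5e4, 6e4)
      shares <- c(0.15, 0.45, 0.40)
    }
    if (n_ages != 3) shares <- rep(1 / n_ages, n_ages)
    jitter <- stats::runif(n_ages, 0.8, 1.2)
    w <- shares * jitter / sum(shares * jitter)
    demand[j, ] <- round(total * w)
  }
  capacity <- capacity_tightness * rowSums(demand)

  structure(list(seed = as.integer(seed), programs = programs,
                 age_groups = ages, models = models, effects = cells,
                 demand = demand, capacity = capacity,
                 capacity_tightness = capacity_tightness,
                 cer_range = cer_range, discount = discount),
            class = "cohort_config")
}

#' Build an allocation problem from a cohort configuration
#'
#' Re-derives every cell's per-participant QALY gain and net cost by running
#' the configured cohort models under the given discounting and horizon, so
#' discount-rate and time-horizon scenarios re-simulate outcomes rather than
#' rescaling them.
#'
#' @param config A `cohort_config` from [generate_config()].
#' @param discount A [discount_spec()]; defaults to the configuration's own.
#' @return An [allocation_problem()].
#' @export
build_problem <- function(config, discount = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(discount)) discount <- config$discount
  stopifnot(inherits(discount, "discount_spec"))
  pr <- config$programs
  ag <- config$age_groups
  rows <- list()
  for (j in seq_len(nrow(pr))) {
    model <- config$models[[pr$population[j]]]
    for (a in seq_len(nrow(ag))) {
      eff <- config$effects[[j]][[a]]$effect
      ev <- evaluate_cell(model, eff, ag$start_age[a], discount)
      rows[[length(rows) + 1]] <- tibble(
        program_code = pr$code[j], program_title = pr$title[j],
        population = pr$population[j], age_label = ag$label[a],
        qaly_per_participant = ev$qaly, cost_per_participant = ev$cost,
        demand = config$demand[j, a], capacity = config$capacity[j]
      )
    }
  }
  cells <- dplyr::bind_rows(rows)
  problem <- allocation_problem(
    cells,
    start_ages = stats::setNames(ag$start_age, ag$label),
    meta = list(discount = discount, generator_seed = config$seed,
                ref_population = 16.4e6)
  )
  attr(problem, "cohort_config") <- config
  problem
}

#' Generate a complete synthetic allocation problem
#'
#' Convenience wrapper: [generate_config()] followed by [build_problem()]
#' under the default discounting (health 1.5%, costs 4%, lifetime horizon).
#' The generating configuration is attached as attribute `cohort_config` so
#' that sensitivity scenarios can re-simulate outcomes.
#'
#' @inheritParams generate_config
#' @return An [allocation_problem()].
#' @export
#' @examples
#' \donttest{
#' problem <- generate_problem(seed = 1)
#' range(cer_table(problem)$average_cer)
#' }
generate_problem <- function(seed, n_programs = 12, n_ages = 3,
                             cer_range = c(1400, 59600),
                             capacity_tightness = 0.6) {
  config <- generate_config(seed, n_programs, n_ages, cer_range,
                            capacity_tightness)
  build_problem(config)
}
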