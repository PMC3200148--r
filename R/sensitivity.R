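#' Remove all capacity constraints from a problem
#'
#' Returns a copy of the problem with every per-program capacity unbounded;
#' all other fields are untouched. Idempotent.
#'
#' @param problem An [allocation_problem()].
#' @return The uncapacitated copy.
#' @export
drop_capacities <- function(problem) {
  stopifnot(inherits(problem, "allocation_problem"))
  problem$capacities$capacity <- Inf
  problem
}

#' Define a sensitivity scenario
#'
#' A scenario varies the structural assumptions of the analysis: whether
#' capacity constraints are active, the discount rates, and the time horizon.
#' Discount-rate and horizon changes require re-simulating per-cell outcomes
#' and therefore a cohort configuration, not just a static problem.
#'
#' @param label Unique scenario label.
#' @param capacities_active Keep the per-program capacity constraints?
#' @param discount Optional [discount_spec()] overriding the base case.
#' @param horizon Optional horizon (years or `"lifetime"`) overriding the
#'   discount spec's horizon.
#' @return A `scenario` object.
#' @export
scenario <- function(label, capacities_active = TRUE, discount = NULL,
                     horizon = NULL) {
  stopifnot(is.character(label), length(label) == 1)
  if (!is.null(discount)) stopifnot(inherits(discount, "discount_spec"))
  structure(list(label = label, capacities_active = capacities_active,
                 discount = discount, horizon = horizon),
            class = "scenario")
}

#' Named scenario presets
#'
#' The study's sensitivity-analysis sets: `"capacity"` (with/without supply
#' limits), `"horizon"` (25 years, 50 years, lifetime), and `"discount"`
#' (both rates 0%, the base case of health 1.5%/costs 4%, both rates 4%, and
#' the widened-differential variant with health at 0% and costs at 4%).
#'
#' @param name Preset name.
#' @return A list of [scenario()] objects.
#' @export
scenario_preset <- function(name = c("capacity", "horizon", "discount")) {
  name <- match.arg(name)
  switch(name,
    capacity = list(
      scenario("with capacities", capacities_active = TRUE),
      scenario("without capacities", capacities_active = FALSE)
    ),
    horizon = list(
      scenario("lifetime", horizon = "lifetime"),
      scenario("50y", horizon = 50),
      scenario("25y", horizon = 25)
    ),
    discount = list(
      scenario("0%/0%", discount = discount_spec(0, 0)),
      scenario("base 1.5%/4%", discount = discount_spec(0.015, 0.04)),
      scenario("4%/4%", discount = discount_spec(0.04, 0.04)),
      scenario("health 0%/costs 4%", discount = discount_spec(0, 0.04))
    )
  )
}

#' Read scenarios from a YAML file
#'
#' Each YAML list entry carries `label` and optionally `capacities_active`,
#' `rate_health`, `rate_cost`, `horizon`. The packaged presets file is at
#' `system.file("extdata", "scenario_presets.yaml", package = "prevalloc")`.
#'
#' @param path Path to a YAML scenario list.
#' @return A list of [scenario()] objects.
#' @export
load_scenarios <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(s) {
    disc <- if (!is.null(s$rate_health) || !is.null(s$rate_cost)) {
      discount_spec(s$rate_health %||% 0.015, s$rate_cost %||% 0.04)
    } else NULL
    scenario(s$label, s$capacities_active %||% TRUE, disc, s$horizon)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_discount <- function(scn, base) {
  d <- scn$discount %||% base
  if (!is.null(scn$horizon)) {
    d <- discount_spec(d$rate_health, d$rate_cost, scn$horizon)
  }
  d
}

#' Compare efficiency frontiers across scenarios
#'
#' Traces one frontier per scenario and evaluates all of them on a shared
#' budget grid (the union of every frontier's breakpoints plus a log-spaced
#' grid up to the largest endpoint), so that pointwise orderings between
#' scenarios are well defined. Scenarios that change discounting or the
#' horizon re-simulate every cell's outcomes from the cohort configuration;
#' passing a static [allocation_problem()] admits only capacity scenarios.
#'
#' @param x A `cohort_config` (from [generate_config()]), an
#'   [allocation_problem()] carrying a `cohort_config` attribute, or a static
#'   [allocation_problem()].
#' @param scenarios A list of [scenario()] objects with unique labels.
#' @param grid_size Number of log-spaced grid budgets added to the shared
#'   breakpoint grid.
#' @return A `scenario_comparison`: list of `frontiers` (named by scenario),
#'   a long tibble `values` with columns `scenario`, `budget`, `qalys`,
#'   `icer`, and the scenario list.
#' @export
scenario_frontiers <- function(x, scenarios, grid_size = 25) {
  if (length(scenarios) == 0) stop("empty scenario list", call. = FALSE)
  labels <- vapply(scenarios, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("scenario labels must be unique", call. = FALSE)

  config <- NULL
  base_problem <- NULL
  if (inherits(x, "cohort_config")) {
    config <- x
  } else if (inherits(x, "allocation_problem")) {
    base_problem <- x
    config <- attr(x, "cohort_config")
  } else {
    stop("x must be a cohort_config or an allocation_problem", call. = FALSE)
  }
  base_discount <- if (!is.null(config)) config$discount else
    (base_problem$meta$discount %||% discount_spec())

  frontiers <- list()
  for (scn in scenarios) {
    needs_resim <- !is.null(scn$discount) || !is.null(scn$horizon)
    if (needs_resim && is.null(config)) {
      stop("scenario '", scn$label, "' changes discounting or the horizon, ",
           "which requires re-simulating per-cell outcomes: supply a ",
           "cohort_config (or a generated problem carrying one), not a ",
           "static problem", call. = FALSE)
    }
    pb <- if (needs_resim || is.null(base_problem)) {
      build_problem(config, scenario_discount(scn, base_discount))
    } else {
      base_problem
    }
    if (!scn$capacities_active) pb <- drop_capacities(pb)
    frontiers[[scn$label]] <- trace_frontier(pb)
  }

  b_max <- max(vapply(frontiers, function(f) f$endpoint$budget, numeric(1)))
  bps <- sort(unique(unlist(lapply(frontiers, function(f)
    c(f$segments$b_lo, f$segments$b_hi)))))
  log_grid <- exp(seq(log(max(b_max * 1e-4, 1)), log(b_max), length.out = grid_size))
  grid <- sort(unique(c(0, bps, log_grid)))

  values <- dplyr::bind_rows(lapply(labels, function(lb) {
    f <- frontiers[[lb]]
    tibble(scenario = lb, budget = grid,
           qalys = frontier_value(f, grid),
           icer = vapply(grid, function(b) frontier_icer_at(f, b), numeric(1)))
  }))
  structure(list(frontiers = frontiers, values = values, scenarios = scenarios),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison> ", length(x$frontiers), " scenarios\n", sep = "")
  for (lb in names(x$frontiers)) {
    f <- x$frontiers[[lb]]
    cat(sprintf("  %-22s endpoint: %s euro -> %s QALYs\n", lb,
                format(round(f$endpoint$budget), big.mark = ","),
                format(round(f$endpoint$qalys, 1), big.mark = ",")))
  }
  invisible(x)
}
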