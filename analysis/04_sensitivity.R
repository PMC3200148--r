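#!/usr/bin/env Rscript

# Sensitivity analyses: capacity limits, time horizons, discount rates.
#
# Re-runs the optimization (i) without the professional-capacity limits,
# (ii) with per-cell outcomes re-simulated at horizons of 25 and 50 years
# against the lifetime reference, and (iii) under the study's discount-rate
# variants (0%/0%, base 1.5%/4%, 4%/4%, health 0%/costs 4%). Writes the
# frontiers in long format on a shared budget grid plus overlay plots.
# Expected pattern: removing capacities and lengthening the horizon move the
# frontier outward; discounting health more heavily moves it inward.

suppressPackageStartupMessages(library(prevalloc))
dir.create("results", showWarnings = FALSE)

seed <- 20 # must match analysis/02_generate_problem.R
problem <- generate_problem(seed = seed)
config <- attr(problem, "cohort_config")

runs <- list(
  capacity = scenario_frontiers(problem, scenario_preset("capacity")),
  horizon = scenario_frontiers(config, scenario_preset("horizon")),
  discount = scenario_frontiers(config, scenario_preset("discount"))
)

long <- dplyr::bind_rows(lapply(names(runs), function(nm) {
  v <- runs[[nm]]$values
  v$analysis <- nm
  v
}))
utils::write.csv(long[, c("analysis", "scenario", "budget", "qalys", "icer")],
                 "results/sensitivity_frontiers.csv", row.names = FALSE)

for (nm in names(runs)) {
  p <- plot_frontiers(runs[[nm]])
  ggplot2::ggsave(sprintf("results/sensitivity_%s.png", nm), p,
                  width = 7, height = 5, dpi = 150)
}

cap <- runs$capacity$frontiers
message(sprintf("capacity removal: endpoint health %s -> %s QALYs (x%.2f), budget %s -> %s EUR",
                format(round(cap[["with capacities"]]$endpoint$qalys), big.mark = ","),
                format(round(cap[["without capacities"]]$endpoint$qalys), big.mark = ","),
                cap[["without capacities"]]$endpoint$qalys /
                  cap[["with capacities"]]$endpoint$qalys,
                format(round(cap[["with capacities"]]$endpoint$budget), big.mark = ","),
                format(round(cap[["without capacities"]]$endpoint$budget), big.mark = ",")))
hz <- runs$horizon$frontiers
message(sprintf("endpoint health by horizon: lifetime %s, 50y %s, 25y %s QALYs",
                format(round(hz[["lifetime"]]$endpoint$qalys), big.mark = ","),
                format(round(hz[["50y"]]$endpoint$qalys), big.mark = ","),
                format(round(hz[["25y"]]$endpoint$qalys), big.mark = ",")))
message("wrote results/sensitivity_frontiers.csv and overlay plots")
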