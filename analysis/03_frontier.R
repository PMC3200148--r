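#!/usr/bin/env Rscript

# Optimal allocations over a range of budgets.
#
# Solves the allocation LP along the whole budget axis: traces the
# efficiency frontier (maximal QALYs per budget, with segment ICERs and the
# cells entering/leaving the optimal portfolio), then tabulates optimal
# allocations on a log-spaced budget grid in the layout of the study's
# budget tables (spend and health shares of the general population, and the
# incremental cost per QALY at that budget). Monetary columns are EUR at
# price level 2007.

suppressPackageStartupMessages(library(prevalloc))
dir.create("results", showWarnings = FALSE)

problem <- load_problem("results/problem.json")
frontier <- trace_frontier(problem)

seg <- frontier$segments
seg_out <- tibble::tibble(
  b_lo = seg$b_lo, b_hi = seg$b_hi, q_lo = seg$q_lo, q_hi = seg$q_hi,
  icer_eur_per_qaly = seg$icer,
  entering = vapply(seg$entering, paste, collapse = " ", character(1)),
  leaving = vapply(seg$leaving, paste, collapse = " ", character(1))
)
utils::write.csv(seg_out, "results/frontier_segments.csv", row.names = FALSE)

budgets <- 10^seq(6, log10(frontier$endpoint$budget), length.out = 10)
rows <- vector("list", length(budgets))
prev <- 0
for (i in seq_along(budgets)) {
  rows[[i]] <- summarize_allocation(problem, budgets[i], frontier = frontier,
                                    reference_budget = prev)
  prev <- budgets[i]
}
summary_tbl <- dplyr::bind_rows(rows)
summary_out <- tibble::tibble(
  budget_eur = summary_tbl$budget,
  pct_spent_general = round(summary_tbl$pct_spend_general),
  total_qalys = summary_tbl$total_qalys,
  pct_gained_general = round(summary_tbl$pct_qaly_general),
  incremental_cost_per_qaly = summary_tbl$icer,
  changes_in_interventions = summary_tbl$changes
)
utils::write.csv(summary_out, "results/budget_summaries.csv", row.names = FALSE)

end <- average_cer_of_endpoint(problem)
message(sprintf("frontier: %d segments, ICERs %s - %s EUR/QALY",
                nrow(seg), format(round(min(seg$icer))),
                format(round(max(seg$icer)))))
message(sprintf("full implementation: %s EUR buys %s QALYs (%s EUR/QALY on average)",
                format(round(end$spend), big.mark = ","),
                format(round(end$qalys), big.mark = ","),
                format(end$rounded, big.mark = ",")))

p <- plot_frontiers(frontier)
ggplot2::ggsave("results/frontier.png", p, width = 7, height = 5, dpi = 150)
message("wrote results/frontier_segments.csv, results/budget_summaries.csv, results/frontier.png")
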