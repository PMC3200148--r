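#!/usr/bin/env Rscript

# Synthetic allocation problem.
#
# Generates the full decision problem the optimizer needs — per-cell QALY
# gains and net costs from the Markov cohort simulator, demand limits and
# per-program capacities — with the study's structure: 12 programs (6 for
# the general population, 6 for diabetes patients) x 3 age groups, all 36
# average cost-effectiveness ratios inside the published league-table range,
# diabetes target groups an order of magnitude smaller, and capacity fixed
# at 60% of each program's total demand. Deterministic in the seed.

suppressPackageStartupMessages(library(prevalloc))
dir.create("results", showWarnings = FALSE)

seed <- 20 # problem instance used throughout the downstream analyses
problem <- generate_problem(seed = seed)

write_problem(problem, "results/problem.csv")
write_problem(problem, "results/problem.json")

ct <- cer_table(problem)
message("generated ", nrow(problem$cells), " cells (seed ", seed, ")")
message("cell CER range: ", round(min(ct$average_cer)), " - ",
        round(max(ct$average_cer)), " EUR/QALY (published range 1400 - 59600)")
dem <- problem_cells(problem)
message("total demand, general: ",
        format(sum(dem$demand[dem$population == "general"]), big.mark = ","),
        "; diabetes: ",
        format(sum(dem$demand[dem$population == "diabetes"]), big.mark = ","))
message("wrote results/problem.csv and results/problem.json")
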