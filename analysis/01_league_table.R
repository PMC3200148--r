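#!/usr/bin/env Rscript

# League table of average cost-effectiveness ratios.
#
# Ranks the 36 intervention-by-age cells of the packaged ratio table
# (12 cardiovascular/diabetes prevention programs x 3 age groups, euro per
# QALY at price level 2007) and counts them in the conventional bands.
# Ranking alone suggests targeted (diabetes) prevention is the better buy at
# low cost-effectiveness thresholds: most cells under 10,000 euro/QALY are
# diabetes cells, while the costliest cells are general-population ones.

suppressPackageStartupMessages(library(prevalloc))
dir.create("results", showWarnings = FALSE)

fx <- cer_fixture()
ranked <- rank_by_cer(fx)
utils::write.csv(ranked, "results/league_table.csv", row.names = FALSE)

bands <- tibble::tibble(
  band_eur_per_qaly = c("(0, 10000)", "(10000, 20000)", "(20000, Inf)"),
  total = c(count_by_cer_band(fx, 0, 10000),
            count_by_cer_band(fx, 10000, 20000),
            count_by_cer_band(fx, 20000, Inf)),
  diabetes = c(count_by_cer_band(fx, 0, 10000, "diabetes"),
               count_by_cer_band(fx, 10000, 20000, "diabetes"),
               count_by_cer_band(fx, 20000, Inf, "diabetes")),
  general = c(count_by_cer_band(fx, 0, 10000, "general"),
              count_by_cer_band(fx, 10000, 20000, "general"),
              count_by_cer_band(fx, 20000, Inf, "general"))
)
utils::write.csv(bands, "results/league_table_bands.csv", row.names = FALSE)

message("cheapest cell:  ", ranked$short_name[1], " (", ranked$age_label[1],
        ", ", ranked$population[1], ") at ", ranked$average_cer[1], " EUR/QALY")
message("costliest cell: ", ranked$short_name[nrow(ranked)], " (",
        ranked$age_label[nrow(ranked)], ", ", ranked$population[nrow(ranked)],
        ") at ", ranked$average_cer[nrow(ranked)], " EUR/QALY")
message("band counts (total / diabetes): ",
        paste(sprintf("%s: %d/%d", bands$band_eur_per_qaly, bands$total,
                      bands$diabetes), collapse = "; "))
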