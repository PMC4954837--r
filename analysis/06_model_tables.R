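#!/usr/bin/env Rscript
# Stage 6 -- daily dyad-level model tables for both initiation directions:
# binary response, standardized ranks, mother presence, running mother-male
# affiliation, paternity/conception indicators, controls and the scan
# offset. Writes results/model_table_{infant,male}.csv.

suppressPackageStartupMessages(library(macaffil))

d <- read_synth_csvs("results/data")
daily <- read.csv("results/daily_ranks.csv", stringsAsFactors = FALSE)
pa <- read.csv("results/paternity.csv", stringsAsFactors = FALSE)
conc <- data.frame(infant = d$conceptions$infant,
                   conc_start = d$conceptions$conc_start,
                   conc_end = d$conceptions$conc_end)

cat("Model tables\n")
for (dir_ in c("infant", "male")) {
  tab <- assemble_model_table(dir_, d$roster, d$memberships, daily,
                              d$scans_daily, d$prox_daily, d$interactions,
                              pa[, c("offspring", "sire")], conc)
  write.csv(tab, sprintf("results/model_table_%s.csv", dir_),
            row.names = FALSE)
  cat(sprintf("  %-6s direction: %6d dyad-days | response rate %.3f | %d infants x %d males\n",
              dir_, nrow(tab), mean(tab$response),
              length(unique(tab$infant)), length(unique(tab$male))))
}
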