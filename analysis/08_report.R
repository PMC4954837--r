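#!/usr/bin/env Rscript
# Stage 8 -- descriptive report: interaction counts and shares, scan
# ratios around mother/male proximity, and sire presence at the end of the
# first year. Writes results/descriptives.json.

suppressPackageStartupMessages({library(macaffil); library(jsonlite)})

d <- read_synth_csvs("results/data")
pa <- read.csv("results/paternity.csv", stringsAsFactors = FALSE)
desc <- descriptives(d$interactions, d$scans_daily, d$prox_daily, d$roster,
                     d$memberships, pa[, c("offspring", "sire")])
print(desc)
write_json(list(
  n_male_infant_interactions = desc$n_male_infant_interactions,
  affiliative_share_pct = desc$affiliative_share_pct,
  infant_initiated_share_pct = desc$infant_initiated_share_pct,
  scans_near_male_mother_absent = desc$scans_near_male_mother_absent,
  scans_near_male_mother_present = desc$scans_near_male_mother_present,
  mother_absent_ratio = desc$mother_absent_ratio,
  male_absent_ratio = desc$male_absent_ratio,
  father_present_at_one_year_pct = desc$father_present_at_one_year_pct),
  "results/descriptives.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/descriptives.json\n")
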