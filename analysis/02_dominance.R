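#!/usr/bin/env Rscript
# Stage 2 -- sequential Elo ratings from the dated agonistic events, then
# daily standardization within (group, sex) to [0,1]. Writes
# results/daily_ranks.csv.

suppressPackageStartupMessages(library(macaffil))

d <- read_synth_csvs("results/data")
tl <- elo_update(d$agonistic, d$memberships)
daily <- elo_standardize(
  elo_daily(tl, d$roster, d$memberships,
            days = seq_len(max(d$memberships$exit))))
write.csv(daily, "results/daily_ranks.csv", row.names = FALSE)

cat("Elo dominance ratings\n")
cat(sprintf("  events processed: %d | rating mass conserved: %s\n",
            nrow(tl$events),
            isTRUE(all.equal(sum(tl$final), length(tl$final) * 1000))))
last <- daily[daily$day == max(daily$day), ]
for (g in sort(unique(last$group))) {
  top <- last[last$group == g & last$sex == "M", ]
  top <- top[order(-top$rating), ]
  cat(sprintf("  %s alpha male: %s (Elo %.0f); lowest: %s (Elo %.0f)\n",
              g, top$id[1L], top$rating[1L], top$id[nrow(top)],
              top$rating[nrow(top)]))
}
cat("  wrote results/daily_ranks.csv\n")
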