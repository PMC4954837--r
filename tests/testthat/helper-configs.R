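# Shared generator configurations for the tests. Sizes are deliberately
# small so the whole suite stays fast; simulation studies in the acceptance
# tests use their own, larger configurations.

# One small group with modest male turnover; enough infants for dyad-day
# tables of a few thousand rows.
tiny_config <- function(seed = 1L, ...) {
  sim_config(n_groups = 1L, females_per_group = 8L, males_per_group = 4L,
             study_days = 400L, focal_age_days = 150L, birth_rate = 5e-3,
             male_mean_tenure_days = 300, male_tenure_sd_days = 180,
             seed = seed, ...)
}

# Stable hierarchy: one group, no male turnover, lots of decided contests.
stable_elo_config <- function(seed = 1L, ...) {
  sim_config(n_groups = 1L, females_per_group = 10L, males_per_group = 10L,
             study_days = 500L, male_mean_tenure_days = 1e6,
             male_tenure_sd_days = 10, birth_rate = 2e-3,
             agonistic_per_group_day = 2.5, seed = seed, ...)
}

# Medium config used for model-fit simulations (no random terms).
fitreco_config <- function(seed = 1L, ...) {
  sim_config(n_groups = 2L, females_per_group = 12L, males_per_group = 5L,
             study_days = 500L, focal_age_days = 180L, birth_rate = 6.5e-3,
             male_mean_tenure_days = 350, male_tenure_sd_days = 200,
             seed = seed, ...)
}

# Construct a handmade genotype table (one row per individual x locus).
geno_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(individual = r[[1L]], locus = r[[2L]], allele1 = r[[3L]],
               allele2 = r[[4L]], status = "het_confirmed",
               stringsAsFactors = FALSE)
  }))
}

# Brute-force Mendelian oracle: candidate compatible at a locus iff some
# (maternal allele, candidate allele) split reproduces the offspring pair.
oracle_mismatches <- function(mother, offspring, candidate) {
  shared <- Reduce(intersect, list(names(mother), names(offspring),
                                   names(candidate)))
  mism <- 0L
  compared <- 0L
  for (l in shared) {
    og <- sort(offspring[[l]])
    mat_ok <- FALSE
    cand_ok <- FALSE
    for (m in mother[[l]]) {
      for (x in unique(c(candidate[[l]], "ZZZ_any"))) {
        if (x == "ZZZ_any") next
        if (identical(sort(c(m, x)), og)) cand_ok <- TRUE
      }
      # is the locus maternally explainable at all (any paternal allele)?
      for (x in og) if (identical(sort(c(m, x)), og)) mat_ok <- TRUE
    }
    if (!mat_ok) next
    compared <- compared + 1L
    if (!cand_ok) mism <- mism + 1L
  }
  list(loci_compared = compared, mismatches = mism)
}

# Random genotype list over `loci` with `k` equifrequent alleles.
random_geno <- function(loci, k = 4L) {
  setNames(lapply(loci, function(l) {
    sort(sample(sprintf("a%d", seq_len(k)), 2L, replace = TRUE))
  }), loci)
}
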