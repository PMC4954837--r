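# Self-contained simulation studies used by the validation suite, the
# analysis drivers and the acceptance script. Each study fixes its own
# scaled-down problem size (documented in the methods vignette) and takes a
# seed so results are reproducible.

#' Type-I error of the dyadic permutation test
#'
#' Simulates independent initiator/recipient event lists (no partner
#' preference) and measures how often the permutation test rejects at
#' `alpha`.
#'
#' @param n_sim number of null datasets.
#' @param n_events events per dataset.
#' @param n_initiators,n_recipients numbers of distinct individuals.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return list with `rejection_rate`, `p_values`, `n_sim`.
#' @export
study_permtest_type1 <- function(n_sim = 500L, n_events = 60L,
                                 n_initiators = 4L, n_recipients = 3L,
                                 n_perm = 200L, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  p <- numeric(n_sim)
  for (b in seq_len(n_sim)) {
    ev <- data.frame(
      initiator = sample(sprintf("i%d", seq_len(n_initiators)), n_events,
                         replace = TRUE),
      recipient = sample(sprintf("m%d", seq_len(n_recipients)), n_events,
                         replace = TRUE),
      stringsAsFactors = FALSE)
    p[b] <- permutation_test(ev, n_perm = n_perm)$p_value
  }
  list(rejection_rate = mean(p <= alpha), p_values = p, n_sim = n_sim)
}

#' True-sire recovery on a synthetic pedigree
#'
#' Generates mothers and candidate males at Hardy-Weinberg equilibrium over
#' equifrequent-allele loci, draws each offspring from its mother and a
#' randomly chosen candidate, produces replicate PCRs with allelic dropout,
#' calls consensus genotypes and runs the exclusion-based assignment with
#' every candidate male in the pool.
#'
#' @param n_offspring,n_candidates pedigree size.
#' @param n_loci,n_alleles marker panel (equifrequent alleles).
#' @param dropout_rate per-allele dropout per PCR replicate.
#' @param pcr_replicates replicates per individual x locus.
#' @param seed integer seed.
#' @return list with `recovery_rate` (assigned-and-correct / offspring),
#'   `wrong_strict_rate` (strictly assigned to a non-sire / strict
#'   assignments), `assignments` (data frame incl. the true sire).
#' @export
study_sire_recovery <- function(n_offspring = 30L, n_candidates = 20L,
                                n_loci = 12L, n_alleles = 6L,
                                dropout_rate = 0.05, pcr_replicates = 8L,
                                seed = 1L) {
  set.seed(seed)
  loci <- sprintf("L%02d", seq_len(n_loci))
  alleles <- sprintf("%d", 100L + 4L * seq_len(n_alleles))
  freq <- setNames(rep(1 / n_alleles, n_alleles), alleles)

  draw_founder <- function() {
    vapply(loci, function(l) sample(alleles, 2L, replace = TRUE),
           character(2L))
  }
  mothers <- lapply(seq_len(n_offspring), function(i) draw_founder())
  males <- lapply(seq_len(n_candidates), function(i) draw_founder())
  names(males) <- sprintf("m%02d", seq_len(n_candidates))
  true_sire <- sample(names(males), n_offspring, replace = TRUE)

  offspring <- lapply(seq_len(n_offspring), function(i) {
    gm <- mothers[[i]]
    gf <- males[[true_sire[i]]]
    vapply(seq_along(loci), function(j) {
      c(gm[sample.int(2L, 1L), j], gf[sample.int(2L, 1L), j])
    }, character(2L))
  })

  # replicate PCRs with dropout -> consensus calls
  reps <- list()
  add_reps <- function(id, g) {
    for (j in seq_along(loci)) {
      for (r in seq_len(pcr_replicates)) {
        shown <- pcr_replicate_call(g[, j], freq, dropout_rate, 0)
        reps[[length(reps) + 1L]] <<- data.frame(
          individual = id, locus = loci[j], replicate = r,
          allele1 = shown[1L],
          allele2 = if (length(shown) > 1L) shown[2L] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (i in seq_len(n_offspring)) {
    colnames(mothers[[i]]) <- colnames(offspring[[i]]) <- loci
    add_reps(sprintf("f%02d", i), mothers[[i]])
    add_reps(sprintf("o%02d", i), offspring[[i]])
  }
  for (m in names(males)) {
    colnames(males[[m]]) <- loci
    add_reps(m, males[[m]])
  }
  genos <- suppressWarnings(
    call_consensus_all(do.call(rbind, reps), on_contamination = "unresolved"))

  cand_g <- setNames(lapply(names(males), get_genotypes, genotypes = genos),
                     names(males))
  out <- lapply(seq_len(n_offspring), function(i) {
    gm <- get_genotypes(genos, sprintf("f%02d", i))
    go <- get_genotypes(genos, sprintf("o%02d", i))
    profs <- lapply(cand_g, function(cg) paternal_mismatches(gm, go, cg))
    asg <- assign_paternity(profs)
    data.frame(offspring = sprintf("o%02d", i), assigned = asg$sire,
               category = asg$category, truth = true_sire[i],
               stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, out)
  strict <- asg[asg$category == "strict", ]
  list(recovery_rate = mean(!is.na(asg$assigned) &
                              asg$assigned == asg$truth),
       wrong_strict_rate = if (nrow(strict) > 0L) {
         mean(strict$assigned != strict$truth)
       } else 0,
       assignments = asg)
}

# Shared generator conditions for the model-fit simulation studies: a
# deliberately scaled-down version of the study system (two groups, ~25
# infants, ~180 focal days) that a plain logistic fit handles in
# milliseconds.
fit_sim_config <- function(seed, ...) {
  sim_config(n_groups = 2L, females_per_group = 12L, males_per_group = 5L,
             study_days = 500L, focal_age_days = 180L, birth_rate = 6.5e-3,
             male_mean_tenure_days = 350, male_tenure_sd_days = 200,
             seed = seed, ...)
}

#' Detection rate of the Gaussian-kernel AC terms under planted AR(1)
#'
#' Repeatedly generates dyad-day data whose logit carries a strong per-dyad
#' AR(1) latent term (`rho`, `sd_latent`), fits the model without and with
#' the two bandwidth-optimized AC terms, and counts how often the AC model
#' improves significantly (likelihood-ratio test at `alpha`, 2 df).
#'
#' @param n_sim number of simulated datasets.
#' @param rho,sd_latent AR(1) parameters of the generator.
#' @param alpha significance level of the improvement test.
#' @param seed integer seed.
#' @return list with `detection_rate`, `chisq` (per-sim statistics),
#'   `rows` (mean table size).
#' @export
study_ac_detection <- function(n_sim = 50L, rho = 0.9, sd_latent = 1,
                               alpha = 0.05, seed = 1L) {
  chisq <- numeric(n_sim)
  rows <- numeric(n_sim)
  sp <- model_spec("infant", include_interactions = FALSE,
                   random_intercepts = character(0L))
  for (s in seq_len(n_sim)) {
    cfg <- sim_config(n_groups = 1L, females_per_group = 10L,
                      males_per_group = 4L, study_days = 450L,
                      focal_age_days = 180L, birth_rate = 6e-3,
                      male_mean_tenure_days = 300, male_tenure_sd_days = 180,
                      ar1_rho = rho, ar1_sd = sd_latent,
                      seed = seed * 1000L + s)
    pop <- simulate_population(cfg)
    tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
    f <- fit_ac_glmm(tt, sp)
    chisq[s] <- lrt(f, f$base_fit)$chisq
    rows[s] <- nrow(tt)
  }
  list(detection_rate = mean(pchisq(chisq, 2L, lower.tail = FALSE) < alpha),
       chisq = chisq, rows = mean(rows))
}

#' Sign recovery of planted fixed effects
#'
#' Generates dyad-day data with the reference effect sizes (male rank
#' +0.15, mother presence -0.2, mother-male affiliation +0.1 on the logit
#' scale), fits the binomial model, and counts the simulations in which
#' every recovered coefficient has the true sign.
#'
#' @param n_sim number of simulated datasets.
#' @param effects named true effects (log-odds).
#' @param seed integer seed.
#' @return list with `all_correct_rate`, `per_effect` (named rates),
#'   `n_sim`.
#' @export
study_sign_recovery <- function(n_sim = 100L,
                                effects = c(male_rank = 0.15,
                                            mother_presence = -0.2,
                                            mother_male_affiliation = 0.1),
                                seed = 1L) {
  sp <- model_spec("infant", include_interactions = FALSE,
                   random_intercepts = character(0L))
  ok <- matrix(NA, n_sim, length(effects),
               dimnames = list(NULL, names(effects)))
  for (s in seq_len(n_sim)) {
    cfg <- fit_sim_config(seed * 1000L + s, true_effects = effects)
    pop <- simulate_population(cfg)
    tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
    f <- fit_binomial(tt, sp)
    est <- setNames(f$coefficients$estimate, f$coefficients$term)
    ok[s, ] <- sign(est[names(effects)]) == sign(effects)
  }
  list(all_correct_rate = mean(rowSums(ok) == length(effects)),
       per_effect = colMeans(ok), n_sim = n_sim)
}

#' Elo recovery of a latent dominance hierarchy
#'
#' Generates a stable group (no migration) with abundant decided agonistic
#' interactions, runs the sequential Elo update, and reports the Spearman
#' correlation between end-of-study ratings and the latent strengths that
#' drove the contests.
#'
#' @param n_adults total adults (half per sex).
#' @param n_events approximate number of contests.
#' @param seed integer seed.
#' @return list with `spearman`, `n_events`.
#' @export
study_elo_recovery <- function(n_adults = 20L, n_events = 1000L, seed = 1L) {
  half <- max(2L, n_adults %/% 2L)
  days <- max(50L, ceiling(n_events / 2))
  cfg <- sim_config(n_groups = 1L, females_per_group = half,
                    males_per_group = half, study_days = days,
                    male_mean_tenure_days = 1e6, male_tenure_sd_days = 10,
                    birth_rate = 0, agonistic_per_group_day = 2,
                    seed = seed)
  pop <- simulate_population(cfg)
  ev <- simulate_agonistic(pop, cfg)
  tl <- elo_update(ev, pop$memberships)
  adults <- pop$roster[pop$roster$class %in% c("adult_female",
                                               "adult_male"), ]
  list(spearman = cor(tl$final[adults$id], adults$strength,
                      method = "spearman"),
       n_events = nrow(ev))
}

#' Full-versus-null degrees of freedom of the dyad-day models
#'
#' Fits the full test-term structure and its null counterpart on a small
#' generated dataset and returns the parameter difference of the
#' likelihood-ratio test (the number of test predictors).
#'
#' @param direction `"infant"` or `"male"`.
#' @param seed integer seed.
#' @return integer LRT df.
#' @export
study_lrt_df <- function(direction = c("infant", "male"), seed = 1L) {
  direction <- match.arg(direction)
  cfg <- fit_sim_config(seed)
  pop <- simulate_population(cfg)
  tt <- truth_model_table(simulate_focal_data(pop, cfg), direction)
  sp <- model_spec(direction, random_intercepts = character(0L))
  full <- fit_binomial(tt, sp)
  null <- fit_binomial(tt, null_spec(sp), fixed_terms = character(0L))
  lrt(full, null)$df
}
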