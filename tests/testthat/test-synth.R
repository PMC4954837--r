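test_that("identical configurations reproduce identical datasets", {
  cfg <- tiny_config(seed = 42L)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$population$roster, b$population$roster)
  expect_identical(a$agonistic, b$agonistic)
  expect_identical(a$focal$truth, b$focal$truth)
  expect_identical(a$genotypes$replicates, b$genotypes$replicates)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(males_per_group = 0), "count >= 1")
  expect_error(sim_config(dropout_rate = 1.2), "probability")
  expect_error(sim_config(ar1_rho = 1), "ar1_rho")
  expect_error(sim_config(true_effects = c(strength = 1)),
               "unknown true_effects")
  expect_silent(sim_config(true_effects = c("male_rank:paternity" = 0.2)))
})

test_that("agonistic events involve co-resident same-sex adults", {
  cfg <- tiny_config(seed = 5L)
  pop <- simulate_population(cfg)
  ev <- simulate_agonistic(pop, cfg)
  expect_gt(nrow(ev), 100L)
  m <- pop$memberships
  ok <- mapply(function(w, l, d, g) {
    any(m$id == w & m$group == g & m$entry <= d & m$exit >= d) &&
      any(m$id == l & m$group == g & m$entry <= d & m$exit >= d)
  }, ev$winner, ev$loser, ev$day, ev$group)
  expect_true(all(ok))
  sex <- setNames(pop$roster$sex, pop$roster$id)
  expect_true(all(sex[ev$winner] == sex[ev$loser]))
})

test_that("extreme paternity skew always assigns the strongest eligible male", {
  cfg <- tiny_config(seed = 9L, paternity_skew = Inf)
  pop <- simulate_population(cfg)
  inf <- pop$roster[pop$roster$class == "infant", ]
  expect_gt(nrow(inf), 0L)
  males <- pop$roster[pop$roster$class == "adult_male", ]
  m <- pop$memberships
  for (i in seq_len(nrow(inf))) {
    elig <- m$id[m$group == inf$group[i] & m$entry <= inf$conc_end[i] &
                   m$exit >= inf$conc_start[i]]
    elig <- intersect(elig, males$id)
    best <- elig[which.max(males$strength[match(elig, males$id)])]
    expect_identical(inf$sire[i], best)
  }
})

test_that("zero paternity skew sires uniformly among eligible males", {
  # stable male pool so every conception has the same five candidates
  cfg <- sim_config(n_groups = 1L, females_per_group = 40L,
                    males_per_group = 5L, study_days = 2500L,
                    male_mean_tenure_days = 1e6, male_tenure_sd_days = 10,
                    birth_rate = 6e-3, birth_spacing_days = 300L,
                    paternity_skew = 0, seed = 77L)
  pop <- simulate_population(cfg)
  sires <- pop$roster$sire[pop$roster$class == "infant"]
  expect_gt(length(sires), 200L)
  tab <- table(factor(sires,
                      levels = pop$roster$id[pop$roster$class == "adult_male"]))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("male tenures follow the configured distribution", {
  cfg <- sim_config(n_groups = 1L, females_per_group = 1L,
                    males_per_group = 4L, study_days = 40000L,
                    birth_rate = 0, seed = 13L)
  pop <- simulate_population(cfg)
  ten <- pop$roster$tenure_days[pop$roster$class == "adult_male"]
  expect_gt(length(ten), 150L)
  expect_lt(abs(mean(ten) - 766.5) / 766.5, 0.10)
})

test_that("noise-free replicate PCRs reproduce the true genotypes exactly", {
  cfg <- tiny_config(seed = 3L, dropout_rate = 0, misprint_rate = 0)
  pop <- simulate_population(cfg)
  gen <- simulate_genotypes(pop, cfg)
  calls <- call_consensus_all(gen$replicates)
  called <- calls[!is.na(calls$allele1), ]
  expect_identical(nrow(called), nrow(gen$truth))
  key <- function(d) paste(d$individual, d$locus, d$allele1, d$allele2)
  expect_setequal(key(called), key(gen$truth))
})

test_that("heterozygote dropout produces single-allele reads at the closed-form rate", {
  d <- 0.2
  cfg <- tiny_config(seed = 8L, dropout_rate = d, misprint_rate = 0,
                     pcr_replicates = 8L)
  pop <- simulate_population(cfg)
  gen <- simulate_genotypes(pop, cfg)
  het <- gen$truth[gen$truth$allele1 != gen$truth$allele2, ]
  reps <- merge(gen$replicates, het[, c("individual", "locus")],
                by = c("individual", "locus"))
  frac_single <- mean(is.na(reps$allele2))
  expected <- 2 * d * (1 - d) + d^2  # at least one allele dropped
  se <- sqrt(expected * (1 - expected) / nrow(reps))
  expect_lt(abs(frac_single - expected), 4 * se)
})

test_that("the infant-initiated share tracks the configured intercepts", {
  # equal intercepts, no effects, no AR noise: share must be ~50%
  cfg <- tiny_config(seed = 21L, true_effects = c(male_rank = 0),
                     intercept_infant = qlogis(0.05),
                     intercept_male = qlogis(0.05), ar1_sd = 0)
  pop <- simulate_population(cfg)
  foc <- simulate_focal_data(pop, cfg)
  ev <- foc$interactions[foc$interactions$behavior != "aggression", ]
  cls <- setNames(pop$roster$class, pop$roster$id)
  share <- mean(cls[ev$initiator] == "infant")
  expect_lt(abs(share - 0.5), 0.05)
})

test_that("every scan row and event references co-resident individuals", {
  cfg <- tiny_config(seed = 30L)
  pop <- simulate_population(cfg)
  foc <- simulate_focal_data(pop, cfg)
  m <- pop$memberships
  px <- foc$prox_daily
  ok <- mapply(function(i, mm, d, g) {
    any(m$id == i & m$group == g & m$entry <= d & m$exit >= d) &&
      any(m$id == mm & m$group == g & m$entry <= d & m$exit >= d)
  }, px$infant, px$male, px$day, px$group)
  expect_true(all(ok))
})
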