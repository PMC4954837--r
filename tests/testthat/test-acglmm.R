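# Naive double-loop reference for the Gaussian-kernel AC term.
ac_oracle <- function(day, key, resid, sigma) {
  n <- length(day)
  out <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (j in seq_len(n)) {
      if (j == i || key[j] != key[i]) next
      w <- exp(-(day[i] - day[j])^2 / (2 * sigma^2))
      num <- num + w * resid[j]
      den <- den + w
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

test_that("AC term reduces to weighted means of same-key residuals", {
  # all same-key residuals equal c: AC = c for any bandwidth
  d <- c(1, 5, 9, 20)
  expect_equal(ac_term(d, rep("a", 4L), rep(0.3, 4L), sigma = 3), rep(0.3, 4L))
  # exactly one partner: its residual, regardless of lag
  expect_equal(ac_term(c(1, 50), c("a", "a"), c(0.7, -0.2), sigma = 2)[1L],
               -0.2)
  # two partners at equal lags: their mean
  expect_equal(ac_term(c(0, 10, 20), rep("a", 3L), c(1, 99, 3),
                       sigma = 4)[2L], 2)
  # no same-key partner: zero
  expect_equal(ac_term(c(1, 2), c("a", "b"), c(1, 1), sigma = 1), c(0, 0))
  expect_error(ac_term(1:3, rep("a", 3L), rep(0, 3L), sigma = 0), "positive")
})

test_that("AC term equals the double-loop oracle to 1e-12", {
  set.seed(6)
  for (rep in 1:3) {
    n <- 400L
    day <- sample.int(120L, n, replace = TRUE)
    key <- sample(letters[1:6], n, replace = TRUE)
    r <- rnorm(n)
    for (sigma in c(0.8, 5, 40)) {
      expect_equal(ac_term(day, key, r, sigma), ac_oracle(day, key, r, sigma),
                   tolerance = 1e-12)
    }
  }
})

test_that("LRT handles identical and nested fits; order of terms is irrelevant", {
  cfg <- tiny_config(seed = 23L)
  pop <- simulate_population(cfg)
  tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
  sp <- model_spec("infant", include_interactions = FALSE,
                   random_intercepts = character(0L))
  f1 <- fit_binomial(tt, sp)
  t0 <- lrt(f1, f1)
  expect_equal(t0$chisq, 0)
  expect_identical(t0$df, 0L)
  expect_equal(t0$p, 1)

  f2 <- fit_binomial(tt, sp, fixed_terms = rev(sp$test_terms))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)

  f0 <- fit_binomial(tt, null_spec(sp), fixed_terms = character(0L))
  t1 <- lrt(f1, f0)
  expect_gte(t1$chisq, 0)
  expect_identical(t1$df, length(sp$test_terms))
})

test_that("VIF matches its closed form and flags perfect collinearity", {
  set.seed(31)
  n <- 400L
  x1 <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ x1))
  x2 <- 0.8 * x1 + sqrt(1 - 0.8^2) * as.numeric(scale(e))  # cor exactly 0.8
  x3 <- as.numeric(scale(residuals(lm(rnorm(n) ~ x1 + x2))))
  d <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  v <- vif_terms(d, c("x1", "x2"))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2L), tolerance = 0.01)
  # orthogonal predictors: VIF 1
  v <- vif_terms(d, c("x1", "x3"))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-6)
  d$x4 <- d$x1
  expect_error(vif_terms(d, c("x1", "x4")), "collinearity")
})

test_that("with no latent heterogeneity the mixed fit matches plain logistic", {
  cfg <- tiny_config(seed = 27L, ar1_sd = 0)
  pop <- simulate_population(cfg)
  tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
  sp_glm <- model_spec("infant", include_interactions = FALSE,
                       random_intercepts = character(0L))
  sp_mix <- model_spec("infant", include_interactions = FALSE,
                       random_intercepts = c("infant", "male"))
  f_glm <- fit_binomial(tt, sp_glm)
  f_mix <- fit_binomial(tt, sp_mix)
  expect_identical(f_mix$method, "Laplace approximation (lme4::glmer)")
  e1 <- setNames(f_glm$coefficients$estimate, f_glm$coefficients$term)
  e2 <- setNames(f_mix$coefficients$estimate, f_mix$coefficients$term)
  expect_equal(e1[names(e2)], e2, tolerance = 1e-3)
})

test_that("bandwidth optimization is deterministic and detects planted AR(1)", {
  cfg <- tiny_config(seed = 44L, ar1_rho = 0.9, ar1_sd = 1)
  pop <- simulate_population(cfg)
  tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
  sp <- model_spec("infant", include_interactions = FALSE,
                   random_intercepts = character(0L))
  f1 <- fit_ac_glmm(tt, sp)
  f2 <- fit_ac_glmm(tt, sp)
  expect_identical(f1$sigma, f2$sigma)
  t <- lrt(f1, f1$base_fit)
  expect_identical(t$df, 2L)
  expect_lt(t$p, 1e-6)

  # lag-1 autocorrelation of dyad-day residuals is clearly positive
  r <- tt$response - fitted(f1$base_fit$model)
  l1 <- unlist(tapply(seq_along(r), tt$dyad, function(ix) {
    if (length(ix) < 3L) return(NULL)
    r[ix[-length(ix)]] * r[ix[-1L]]
  }))
  expect_gt(mean(l1), 0)
})

test_that("AC terms detect planted AR(1) across replicate datasets", {
  # strong per-dyad AR(1): the refitted model with both optimized AC terms
  # must improve significantly on the AC-free fit, replicate after replicate
  sp <- model_spec("infant", include_interactions = FALSE,
                   random_intercepts = character(0L))
  for (s in c(46L, 47L, 50L)) {
    cfg <- tiny_config(seed = s, ar1_rho = 0.9, ar1_sd = 1)
    pop <- simulate_population(cfg)
    tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
    f <- fit_ac_glmm(tt, sp)
    expect_lt(lrt(f, f$base_fit)$p, 0.05)
  }
})

test_that("planted fixed effects are recovered and nulls stay centred", {
  # effect recovery: the male-rank coefficient covers its truth
  est <- se <- numeric(30L)
  for (s in seq_len(30L)) {
    cfg <- tiny_config(seed = 300L + s, ar1_sd = 0,
                       true_effects = c(male_rank = 0.5))
    pop <- simulate_population(cfg)
    tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
    sp <- model_spec("infant", include_interactions = FALSE,
                     random_intercepts = character(0L))
    f <- fit_binomial(tt, sp)
    k <- match("male_rank", f$coefficients$term)
    est[s] <- f$coefficients$estimate[k]
    se[s] <- f$coefficients$se[k]
  }
  covered <- mean(abs(est - 0.5) <= 1.96 * se)
  expect_gte(covered, 0.85)

  # null generator: estimates centred on zero
  est0 <- numeric(30L)
  for (s in seq_len(30L)) {
    cfg <- tiny_config(seed = 600L + s, ar1_sd = 0,
                       true_effects = c(male_rank = 0))
    pop <- simulate_population(cfg)
    tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
    sp <- model_spec("infant", include_interactions = FALSE,
                     random_intercepts = character(0L))
    f <- fit_binomial(tt, sp)
    est0[s] <- f$coefficients$estimate[match("male_rank",
                                             f$coefficients$term)]
  }
  expect_lt(abs(mean(est0)), 2 * sd(est0) / sqrt(30))
})

test_that("interaction pruning is hierarchical and follows the signal", {
  # a planted rank x bond interaction is retained, and the pruning log
  # never leaves an interaction without its main effects
  cfg <- fitreco_config(seed = 88L, ar1_sd = 0,
                        true_effects = c(male_rank = 0.15,
                                         mother_presence = -0.2,
                                         mother_male_affiliation = 0.1,
                                         "male_rank:mother_male_affiliation" = 0.3))
  pop <- simulate_population(cfg)
  tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
  sp <- model_spec("infant", random_intercepts = character(0L))
  pr <- prune_interactions(tt, sp, with_ac = FALSE)
  expect_true("male_rank:mother_male_affiliation" %in% pr$final_terms)
  for (tm in grep(":", pr$final_terms, value = TRUE)) {
    parts <- strsplit(tm, ":")[[1L]]
    expect_true(all(parts %in% pr$final_terms))
  }
  expect_true(all(c("three_way", "two_way") %in% pr$log$tier))

  # under a null generator no interaction should survive at this seed
  cfg0 <- tiny_config(seed = 89L, ar1_sd = 0,
                      true_effects = c(male_rank = 0))
  pop0 <- simulate_population(cfg0)
  tt0 <- truth_model_table(simulate_focal_data(pop0, cfg0), "infant")
  pr0 <- prune_interactions(tt0, sp, with_ac = FALSE)
  expect_identical(grep(":", pr0$final_terms, value = TRUE), character(0L))
})

test_that("stability check exposes a planted influential subject", {
  cfg <- tiny_config(seed = 52L, ar1_sd = 0)
  pop <- simulate_population(cfg)
  tt <- truth_model_table(simulate_focal_data(pop, cfg), "infant")
  planted <- names(which.max(table(tt$infant)))
  tt$response[tt$infant == planted] <- 1L  # pathological always-affiliating
  sp <- model_spec("infant", include_interactions = FALSE,
                   random_intercepts = character(0L))
  st <- stability_check(tt, sp, groups = "infant")
  expect_identical(sort(unique(st$level)), sort(unique(tt$infant)))
  ic <- st[st$term == "(Intercept)", ]
  # dropping the pathological infant moves the intercept far more than a
  # typical exclusion does
  d_planted <- abs(ic$delta[ic$level == planted])
  d_typical <- stats::median(abs(ic$delta[ic$level != planted]))
  expect_gt(d_planted, 3 * d_typical)
})
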