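test_that("multi-tube consensus rules call het, hom and unresolved correctly", {
  # het: both alleles confirmed twice across four PCRs
  r <- list(c("A", "B"), c("A", "B"), "A", "B")
  res <- call_consensus(r)
  expect_identical(res$status, "het_confirmed")
  expect_identical(res$call, c("A", "B"))

  # hom: a single allele in six independent PCRs
  res <- call_consensus(rep(list("A"), 6L))
  expect_identical(res$status, "hom_confirmed")
  expect_identical(res$call, c("A", "A"))

  # extended run: stray het read never reconfirmed does not block the call
  r <- c(rep(list("A"), 5L), list(c("A", "B")), rep(list("A"), 5L))
  res <- call_consensus(r)
  expect_identical(res$status, "hom_confirmed")
  expect_identical(res$call, c("A", "A"))

  # two alleles confirmed but fewer than four PCRs: unresolved
  expect_identical(call_consensus(list(c("A", "B"), c("A", "B")))$status,
                   "unresolved")
  # five consistent reads are not yet enough for a homozygote
  expect_identical(call_consensus(rep(list("A"), 5L))$status, "unresolved")

  # replicate order is irrelevant
  r <- list("A", c("A", "B"), "B", c("A", "B"), "A")
  for (i in 1:5) {
    expect_identical(call_consensus(sample(r))$call, c("A", "B"))
  }

  # three alleles each confirmed twice: contamination
  r <- list(c("A", "B"), c("A", "B"), c("A", "C"), c("A", "C"), c("B", "C"))
  expect_error(call_consensus(r), "contamination")
})

test_that("allele frequencies are gene counts and order-invariant", {
  g <- geno_df(list("i1", "L1", "A", "A"), list("i2", "L1", "A", "B"))
  f <- allele_frequencies(g)
  expect_equal(f$freq[f$allele == "A"], 0.75)
  expect_equal(f$freq[f$allele == "B"], 0.25)
  f2 <- allele_frequencies(g[2:1, ])
  expect_equal(f[order(f$allele), ], f2[order(f2$allele), ],
               ignore_attr = TRUE)
  # all homozygous: frequency 1
  g3 <- geno_df(list("i1", "L1", "A", "A"), list("i2", "L1", "A", "A"))
  expect_equal(allele_frequencies(g3)$freq, 1)
})

test_that("locus summaries match hand-computed Ho and PIC", {
  # two equifrequent alleles: PIC = 1 - 0.5 - 0.125 = 0.375
  g <- geno_df(list("i1", "L1", "A", "A"), list("i2", "L1", "B", "B"),
               list("i3", "L1", "A", "B"), list("i4", "L1", "A", "B"))
  s <- locus_summary(g)
  expect_equal(s$PIC, 0.375)
  expect_equal(s$Ho, 0.5)
  expect_equal(s$He, 0.5)
  expect_equal(s$null_allele_index, 0)

  # monomorphic: Ho = PIC = 0
  g <- geno_df(list("i1", "L1", "A", "A"), list("i2", "L1", "A", "A"))
  s <- locus_summary(g)
  expect_equal(s$Ho, 0)
  expect_equal(s$PIC, 0)

  # everyone heterozygous: Ho = 1
  g <- geno_df(list("i1", "L1", "A", "B"), list("i2", "L1", "A", "B"))
  expect_equal(locus_summary(g)$Ho, 1)
})

test_that("null-allele index follows its closed form", {
  expect_equal(null_allele_index(0.5, 0.5), 0)
  expect_equal(null_allele_index(0, 0.5), 1)
  expect_equal(null_allele_index(0.6, 0.5), -1 / 11)
  expect_true(is.na(null_allele_index(0.3, 0)))
})

test_that("Hardy-Weinberg Monte Carlo test behaves at both extremes", {
  # counts exactly at Hardy-Weinberg proportions: p near 1
  mat <- cbind(c(rep("A", 25), rep("B", 25), rep("A", 50)),
               c(rep("A", 25), rep("B", 25), rep("B", 50)))
  expect_gt(hwe_test(mat, n_perm = 500L, seed = 1L), 0.5)

  # all heterozygotes: a gross violation
  mat <- cbind(rep("A", 50), rep("B", 50))
  expect_lt(hwe_test(mat, n_perm = 2000L, seed = 1L), 0.01)

  # monomorphic locus: p = 1 by convention
  mat <- cbind(rep("A", 10), rep("A", 10))
  expect_equal(hwe_test(mat), 1)
})

test_that("HWE rejection rate under the null is close to nominal", {
  set.seed(99)
  n_rep <- 200L
  rej <- logical(n_rep)
  for (b in seq_len(n_rep)) {
    p <- c(0.4, 0.3, 0.2, 0.1)
    a1 <- sample(letters[1:4], 40L, replace = TRUE, prob = p)
    a2 <- sample(letters[1:4], 40L, replace = TRUE, prob = p)
    rej[b] <- hwe_test(cbind(a1, a2), n_perm = 200L) <= 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.045)
})

test_that("probabilities of identity match their closed forms", {
  v <- pid_single(c(0.5, 0.5))
  expect_equal(unname(v["pid"]), 0.375)
  expect_equal(unname(v["pidsib"]), 0.59375)
  v <- pid_single(rep(0.25, 4))
  expect_equal(unname(v["pid"]), 0.109375)
  expect_equal(unname(v["pidsib"]), 0.40234375)

  # PIDsib dominates PID; multi-locus products decrease with added loci
  for (k in 2:6) {
    p <- rep(1 / k, k)
    v <- pid_single(p)
    expect_gte(v[["pidsib"]], v[["pid"]])
  }
  freqs <- do.call(rbind, lapply(1:5, function(l) {
    data.frame(locus = sprintf("L%d", l), allele = c("A", "B"), freq = 0.5)
  }))
  prods <- vapply(1:5, function(k) {
    pid_multi(freqs, sprintf("L%d", 1:k))$pidsib
  }, numeric(1L))
  expect_true(all(diff(prods) < 0))
})

test_that("minimum locus count for identity matches the cumulative product", {
  freqs <- do.call(rbind, lapply(1:12, function(l) {
    data.frame(locus = sprintf("L%02d", l), allele = c("A", "B"), freq = 0.5)
  }))
  # each locus has PIDsib 0.59375; hand arithmetic gives 0.59375^9 < 0.01
  r <- min_loci_for_identity(freqs, threshold = 0.01)
  expect_identical(r$n_loci, 9L)
  expect_equal(r$pidsib_cumulative, 0.59375^9)
  expect_true(r$attainable)
  # threshold 1 is met by any single locus
  expect_identical(min_loci_for_identity(freqs, 1)$n_loci, 1L)
  # unattainable: flagged, all loci reported
  r <- min_loci_for_identity(freqs, 1e-6)
  expect_false(r$attainable)
  expect_identical(r$n_loci, 12L)
  # on only 8 available loci the same threshold cannot be met
  r8 <- min_loci_for_identity(freqs[1:16, ], 0.01)  # first 8 loci
  expect_false(r8$attainable)
  expect_identical(r8$n_loci, 8L)
})
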