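mk_geno <- function(pairs) lapply(pairs, sort)

test_that("maternity confirmation shares an allele at every compared locus", {
  loci <- sprintf("L%02d", 1:9)
  mother <- setNames(rep(list(c("A", "B")), 9L), loci)
  offspring <- setNames(rep(list(c("B", "C")), 9L), loci)
  r <- confirm_maternity(mother, offspring)
  expect_true(r$confirmed)
  expect_identical(r$loci_compared, 9L)

  # one mismatching locus is reported
  offspring$L05 <- c("C", "D")
  mother$L05 <- c("A", "A")
  r <- confirm_maternity(mother, offspring)
  expect_false(r$confirmed)
  expect_identical(r$mismatch_loci, "L05")

  # a missing locus is skipped, not counted as compared
  offspring$L05 <- NULL
  r <- confirm_maternity(mother, offspring)
  expect_true(r$confirmed)
  expect_identical(r$loci_compared, 8L)

  # too few shared loci is an explicit error
  expect_error(confirm_maternity(mother[1:5], offspring[1:5]),
               "insufficient")
})

test_that("paternal mismatch deduction handles obligate and ambiguous alleles", {
  # obligate paternal allele carried: no mismatch
  p <- paternal_mismatches(mk_geno(list(L1 = c("A", "B"))),
                           mk_geno(list(L1 = c("A", "C"))),
                           mk_geno(list(L1 = c("C", "D"))))
  expect_identical(p$mismatches, 0L)
  # obligate allele absent: one mismatch
  p <- paternal_mismatches(mk_geno(list(L1 = c("A", "B"))),
                           mk_geno(list(L1 = c("A", "C"))),
                           mk_geno(list(L1 = c("D", "E"))))
  expect_identical(p$mismatches, 1L)
  expect_identical(p$mismatch_loci, "L1")
  # both offspring alleles maternal: either may be paternal
  p <- paternal_mismatches(mk_geno(list(L1 = c("A", "B"))),
                           mk_geno(list(L1 = c("A", "B"))),
                           mk_geno(list(L1 = c("B", "E"))))
  expect_identical(p$mismatches, 0L)
})

test_that("mismatch counts agree with a brute-force Mendelian-split oracle", {
  set.seed(7)
  loci <- sprintf("L%02d", 1:8)
  for (trio in 1:300) {
    gm <- random_geno(loci)
    go <- random_geno(loci)
    gc <- random_geno(loci)
    # drop a random locus from each genotype to exercise the skip rule
    gm[[sample.int(8L, 1L)]] <- NULL
    gc[[sample.int(7L, 1L)]] <- NULL
    mine <- paternal_mismatches(gm, go, gc)
    orac <- oracle_mismatches(gm, go, gc)
    expect_identical(mine$mismatches, orac$mismatches)
    expect_identical(mine$loci_compared, orac$loci_compared)
  }
})

test_that("removing loci can only keep or reduce the mismatch count", {
  set.seed(8)
  loci <- sprintf("L%02d", 1:10)
  for (trio in 1:50) {
    gm <- random_geno(loci); go <- random_geno(loci); gc <- random_geno(loci)
    full <- paternal_mismatches(gm, go, gc)$mismatches
    sub <- paternal_mismatches(gm, go, gc[sample(loci, 6L)])$mismatches
    expect_lte(sub, full)
  }
})

test_that("exclusion categories and conception tie-breaking assign as specified", {
  mm <- function(...) {
    v <- c(...)
    data.frame(candidate = names(v), mismatches = unname(v))
  }
  r <- assign_paternity(mm(m1 = 0L, m2 = 3L, m3 = 2L))
  expect_identical(r$category, "strict")
  expect_identical(r$sire, "m1")

  r <- assign_paternity(mm(m1 = 0L, m2 = 1L, m3 = 2L))
  expect_identical(r$category, "standard")
  expect_identical(r$sire, "m1")

  r <- assign_paternity(mm(m1 = 1L, m2 = 2L, m3 = 4L))
  expect_identical(r$category, "relaxed")
  expect_identical(r$sire, "m1")

  # two mismatch-free males: presence at conception decides
  r <- assign_paternity(mm(m1 = 0L, m2 = 0L, m3 = 2L),
                        present_at_conception = c(m1 = FALSE, m2 = TRUE,
                                                  m3 = TRUE))
  expect_identical(r$category, "tiebreak_conception")
  expect_identical(r$sire, "m2")

  # both present: unresolved
  r <- assign_paternity(mm(m1 = 0L, m2 = 0L),
                        present_at_conception = c(m1 = TRUE, m2 = TRUE))
  expect_identical(r$category, "unresolved")
  expect_true(is.na(r$sire))

  # two males with one mismatch each: not relaxed
  r <- assign_paternity(mm(m1 = 1L, m2 = 1L, m3 = 3L))
  expect_identical(r$category, "unresolved")
})

test_that("LOD scores match the hand-computed transition-probability ratio", {
  freqs <- data.frame(locus = "L1", allele = c("A", "B"), freq = 0.5)
  gm <- list(L1 = c("A", "A"))
  go <- list(L1 = c("A", "A"))
  gc <- list(L1 = c("A", "A"))
  expect_equal(lod_score(gm, go, gc, freqs, error_rate = 0), log(2))
  # incompatible candidate at zero error rate: -Inf
  expect_identical(lod_score(gm, go, list(L1 = c("B", "B")), freqs,
                             error_rate = 0), -Inf)
  # with a positive error rate the penalty is finite
  expect_true(is.finite(lod_score(gm, go, list(L1 = c("B", "B")), freqs,
                                  error_rate = 0.01)))
})

test_that("the true sire outscores random non-sires in simulated trios", {
  set.seed(15)
  loci <- sprintf("L%02d", 1:12)
  freqs <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus = l, allele = sprintf("a%d", 1:4), freq = 0.25)
  }))
  wins <- 0L
  n_trio <- 60L
  for (i in seq_len(n_trio)) {
    gm <- random_geno(loci); gf <- random_geno(loci); gr <- random_geno(loci)
    go <- setNames(lapply(loci, function(l) {
      sort(c(sample(gm[[l]], 1L), sample(gf[[l]], 1L)))
    }), loci)
    if (lod_score(gm, go, gf, freqs) > lod_score(gm, go, gr, freqs)) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins / n_trio, 0.95)
})

test_that("assignment confidence is 0 without information and high with 12 informative loci", {
  loci <- sprintf("L%02d", 1:12)
  # monomorphic panel: every candidate ties, never strictly best
  freqs1 <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus = l, allele = "A", freq = 1)
  }))
  mono <- setNames(rep(list(c("A", "A")), 12L), loci)
  cands <- list(m1 = mono, m2 = mono)
  expect_equal(delta_confidence(mono, mono, cands, freqs1, n_sim = 50L,
                                seed = 1L), 0)

  # informative panel
  set.seed(33)
  freqs2 <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus = l, allele = sprintf("a%d", 1:6), freq = 1 / 6)
  }))
  gm <- random_geno(loci, k = 6L)
  cands <- setNames(lapply(1:10, function(i) random_geno(loci, k = 6L)),
                    sprintf("m%d", 1:10))
  conf <- delta_confidence(gm, cands$m1, cands, freqs2, n_sim = 200L,
                           error_rate = 0.01, seed = 2L, sire_id = "m1")
  expect_gte(conf, 0.95)
})

test_that("paternity is recovered end to end on a noisy synthetic pedigree", {
  cfg <- tiny_config(seed = 19L, dropout_rate = 0.05, misprint_rate = 0,
                     pcr_replicates = 8L)
  pop <- simulate_population(cfg)
  gen <- simulate_genotypes(pop, cfg)
  genos <- suppressWarnings(
    call_consensus_all(gen$replicates, on_contamination = "unresolved"))
  inf <- pop$roster[pop$roster$class == "infant", ]
  ot <- data.frame(offspring = inf$id, mother = inf$mother,
                   group = inf$group, conc_start = inf$conc_start,
                   conc_end = inf$conc_end, stringsAsFactors = FALSE)
  males <- pop$roster$id[pop$roster$class == "adult_male"]
  pa <- paternity_analysis(genos, ot, males, pop$memberships)
  assigned <- !is.na(pa$sire)
  expect_gt(mean(assigned), 0.8)
  expect_true(all(pa$sire[assigned] ==
                    inf$sire[match(pa$offspring, inf$id)][assigned]))
})
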