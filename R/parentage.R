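#' Extract one individual's genotypes as a named list
#'
#' @param genotypes data frame with `individual`, `locus`, `allele1`,
#'   `allele2`.
#' @param id individual identifier.
#' @return named list mapping locus to a sorted character pair; loci with
#'   missing calls are omitted.
#' @export
get_genotypes <- function(genotypes, id) {
  g <- genotypes[genotypes$individual == id &
                   !is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
  setNames(lapply(seq_len(nrow(g)),
                  function(i) sort(c(g$allele1[i], g$allele2[i]))),
           g$locus)
}

#' Genetic confirmation of observed maternity
#'
#' Mother and offspring must share at least one allele at every locus where
#' both are called; loci missing in either are skipped and not counted as
#' compared. At least `min_loci` shared called loci are required.
#'
#' @param mother,offspring genotype lists from [get_genotypes()].
#' @param min_loci minimum shared called loci (default 8).
#' @return list with `confirmed` (logical), `loci_compared`, and
#'   `mismatch_loci`.
#' @export
confirm_maternity <- function(mother, offspring, min_loci = 8L) {
  shared <- intersect(names(mother), names(offspring))
  if (length(shared) < min_loci) {
    stop_data("insufficient data: only %d shared called loci (need >= %d)",
              length(shared), min_loci)
  }
  mism <- shared[vapply(shared, function(l) {
    length(intersect(mother[[l]], offspring[[l]])) == 0L
  }, logical(1))]
  list(confirmed = length(mism) == 0L, loci_compared = length(shared),
       mismatch_loci = mism)
}

# Possible paternal alleles at one locus: an offspring allele is a possible
# paternal contribution iff the other offspring allele can have come from
# the mother. Empty when the mother-offspring pair itself mismatches.
possible_paternal_alleles <- function(mother_g, offspring_g) {
  o1 <- offspring_g[1L]; o2 <- offspring_g[2L]
  out <- character(0L)
  if (o2 %in% mother_g) out <- c(out, o1)
  if (o1 %in% mother_g) out <- c(out, o2)
  unique(out)
}

#' Paternal-exclusion mismatch profile for one candidate male
#'
#' At each locus called in all three of mother, offspring and candidate, the
#' paternal allele set is deduced from the mother-offspring pair: if both
#' offspring alleles could be maternal, either allele may be paternal and
#' the candidate is compatible when he carries at least one of them;
#' otherwise he must carry the obligate paternal allele. Each incompatible
#' locus adds one mismatch. Loci with a missing call in any of the three
#' genotypes are skipped and not counted as compared, as are loci where the
#' mother-offspring pair itself mismatches.
#'
#' @param mother,offspring,candidate genotype lists from [get_genotypes()].
#' @return list with `loci_compared`, `mismatches`, `mismatch_loci`.
#' @export
paternal_mismatches <- function(mother, offspring, candidate) {
  shared <- Reduce(intersect, list(names(mother), names(offspring),
                                   names(candidate)))
  mism <- character(0L)
  compared <- 0L
  for (l in shared) {
    pat <- possible_paternal_alleles(mother[[l]], offspring[[l]])
    if (length(pat) == 0L) next  # maternal mismatch: not informative
    compared <- compared + 1L
    if (!any(pat %in% candidate[[l]])) mism <- c(mism, l)
  }
  list(loci_compared = compared, mismatches = length(mism),
       mismatch_loci = mism)
}

#' Assign paternity by exclusion categories with conception tie-breaking
#'
#' Given the mismatch counts of every candidate male, assigns the sire by
#' category precedence:
#' \describe{
#'   \item{strict}{exactly one candidate without mismatch, all others
#'     excluded on at least two loci;}
#'   \item{standard}{exactly one candidate without mismatch, all others
#'     excluded on at least one locus;}
#'   \item{relaxed}{no mismatch-free candidate, exactly one candidate with a
#'     single mismatch and all others with at least two;}
#'   \item{tiebreak_conception}{several mismatch-free candidates, exactly
#'     one of whom was present in the offspring's group during the
#'     conceptive window;}
#'   \item{unresolved}{anything else (no sire assigned).}
#' }
#'
#' @param profiles named list of [paternal_mismatches()] results (names =
#'   candidate ids), or a data frame with columns `candidate` and
#'   `mismatches`.
#' @param present_at_conception named logical vector: was each candidate
#'   present in the offspring's group during the conceptive window (used
#'   only for tie-breaking; may be omitted when no tie occurs).
#' @return list with `sire` (id or `NA`), `category`, and `mismatches`
#'   (named integer vector over candidates).
#' @export
assign_paternity <- function(profiles, present_at_conception = NULL) {
  if (is.data.frame(profiles)) {
    mm <- setNames(as.integer(profiles$mismatches), profiles$candidate)
  } else {
    mm <- vapply(profiles, function(p) as.integer(p$mismatches), integer(1L))
  }
  if (length(mm) < 1L) stop_data("at least one candidate profile is required")
  zero <- names(mm)[mm == 0L]
  if (length(zero) == 1L) {
    others <- mm[names(mm) != zero]
    cat <- if (length(others) == 0L || all(others >= 2L)) "strict" else "standard"
    return(list(sire = zero, category = cat, mismatches = mm))
  }
  if (length(zero) == 0L) {
    one <- names(mm)[mm == 1L]
    if (length(one) == 1L && all(mm[names(mm) != one] >= 2L)) {
      return(list(sire = one, category = "relaxed", mismatches = mm))
    }
    return(list(sire = NA_character_, category = "unresolved",
                mismatches = mm))
  }
  # several mismatch-free candidates: conception presence breaks the tie
  pres <- present_at_conception[zero]
  if (!is.null(present_at_conception) && sum(pres %in% TRUE) == 1L) {
    return(list(sire = zero[which(pres %in% TRUE)],
                category = "tiebreak_conception", mismatches = mm))
  }
  list(sire = NA_character_, category = "unresolved", mismatches = mm)
}

# Mendelian transmission probability of observing offspring pair `og`
# given mother pair `mg` and a paternal allele distribution `pat`
# (named probabilities).
transmission_prob <- function(og, mg, pat) {
  t_m <- function(x) mean(mg == x)
  f <- function(x) if (x %in% names(pat)) pat[[x]] else 0
  if (og[1L] == og[2L]) {
    t_m(og[1L]) * f(og[1L])
  } else {
    t_m(og[1L]) * f(og[2L]) + t_m(og[2L]) * f(og[1L])
  }
}

#' Paternity LOD score with a genotyping-error model
#'
#' Natural-log likelihood ratio, summed over loci, of the offspring genotype
#' arising with the candidate as sire versus with a random sire drawn from
#' the population allele frequencies. Each locus likelihood is a mixture
#' `(1 - e) * Mendelian + e * HWE-random` (a single per-locus error rate in
#' the style of standard parentage-likelihood constructions), so genuine
#' mismatches are penalized but not infinitely when `error_rate > 0`. At
#' `error_rate = 0` an incompatible candidate yields `-Inf`. Loci missing in
#' any genotype (or without frequencies) are skipped.
#'
#' @param mother,offspring,candidate genotype lists from [get_genotypes()].
#' @param freqs allele-frequency table ([allele_frequencies()]).
#' @param error_rate per-locus genotyping error rate in `[0, 0.5)`.
#' @return the LOD score (natural log).
#' @export
lod_score <- function(mother, offspring, candidate, freqs, error_rate = 0.01) {
  if (error_rate < 0 || error_rate >= 0.5) {
    stop_data("error_rate must lie in [0, 0.5)")
  }
  shared <- Reduce(intersect, list(names(mother), names(offspring),
                                   names(candidate)))
  total <- 0
  for (l in shared) {
    fl <- freqs[freqs$locus == l, ]
    if (nrow(fl) == 0L) next
    pop <- setNames(fl$freq, fl$allele)
    og <- offspring[[l]]; mg <- mother[[l]]; cg <- candidate[[l]]
    pat_c <- as.list(table(cg) / length(cg))  # candidate transmission probs
    p_hwe <- if (og[1L] == og[2L]) {
      pop_f(pop, og[1L])^2
    } else {
      2 * pop_f(pop, og[1L]) * pop_f(pop, og[2L])
    }
    num <- (1 - error_rate) * transmission_prob(og, mg, pat_c) +
      error_rate * p_hwe
    den <- (1 - error_rate) * transmission_prob(og, mg, as.list(pop)) +
      error_rate * p_hwe
    if (den <= 0) next  # offspring impossible under both: uninformative
    total <- total + (if (num <= 0) -Inf else log(num / den))
  }
  total
}

pop_f <- function(pop, a) if (a %in% names(pop)) pop[[a]] else 0

#' Simulation-based confidence of a paternity assignment
#'
#' A simplified simulation-based confidence level: `n_sim` offspring are
#' simulated from the observed mother and the assigned sire (Mendelian
#' inheritance, then each allele substituted with probability `error_rate`
#' by a random allele from the population frequencies), and for each
#' simulated offspring the LOD of every candidate male is computed. The
#' confidence is the proportion of simulations in which the assigned sire
#' attains the strictly highest LOD among all candidates, i.e. the
#' probability that an offspring truly sired by him would be recovered
#' unambiguously given this candidate pool and marker panel. Uninformative
#' panels (e.g. monomorphic loci) give 0 because ties are never strict;
#' informative panels approach 1.
#'
#' @param mother genotype list of the mother.
#' @param sire genotype list of the assigned sire.
#' @param candidates named list of genotype lists for the full candidate
#'   pool (must include the assigned sire).
#' @param freqs allele-frequency table.
#' @param n_sim number of simulated offspring (>= 1000 for stable
#'   estimates).
#' @param error_rate observation error applied to simulated offspring and
#'   used in the LOD computation.
#' @param seed optional integer seed.
#' @param sire_id name of the assigned sire within `candidates` (defaults
#'   to matching by identity of the genotype list).
#' @return confidence in `[0, 1]`.
#' @export
delta_confidence <- function(mother, sire, candidates, freqs, n_sim = 1000L,
                             error_rate = 0.01, seed = NULL, sire_id = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sire_id)) {
    hit <- which(vapply(candidates, identical, logical(1L), sire))
    if (length(hit) == 0L) stop_data("assigned sire not found among candidates")
    sire_id <- names(candidates)[hit[1L]]
  }
  loci <- intersect(names(mother), names(sire))
  pop <- split(setNames(freqs$freq, freqs$allele), freqs$locus)
  wins <- 0L
  for (s in seq_len(n_sim)) {
    off <- setNames(lapply(loci, function(l) {
      a <- c(sample(mother[[l]], 1L), sample(sire[[l]], 1L))
      err <- runif(2L) < error_rate
      if (any(err)) {
        p <- pop[[l]]
        a[err] <- sample(names(p), sum(err), replace = TRUE, prob = p)
      }
      sort(a)
    }), loci)
    lods <- vapply(candidates, function(cg) {
      lod_score(mother, off, cg, freqs, error_rate)
    }, numeric(1L))
    best <- max(lods)
    if (is.finite(best) && lods[[sire_id]] == best &&
        sum(lods >= best - 1e-9) == 1L) {
      wins <- wins + 1L
    }
  }
  wins / n_sim
}

#' Full paternity analysis for a set of offspring
#'
#' Confirms maternity, profiles every candidate male, applies the exclusion
#' categories with conception-presence tie-breaking, and attaches the LOD
#' score of the assigned sire.
#'
#' @param genotypes consensus genotype table ([call_consensus_all()]).
#' @param offspring_tab data frame with `offspring`, `mother`, `group`,
#'   `conc_start`, `conc_end`.
#' @param candidates character vector of candidate male ids (typically all
#'   genotyped adult males ever resident in the study groups).
#' @param memberships membership table for conception-presence lookups.
#' @param freqs allele-frequency table; computed from `genotypes` when
#'   omitted.
#' @param error_rate LOD error rate.
#' @param min_maternity_loci minimum shared loci for the maternity check.
#' @return data frame with one row per offspring: `offspring`, `sire`,
#'   `category`, `lod`, `maternity_confirmed`, `n_candidates`.
#' @export
paternity_analysis <- function(genotypes, offspring_tab, candidates,
                               memberships, freqs = NULL, error_rate = 0.01,
                               min_maternity_loci = 8L) {
  need_cols(offspring_tab,
            c("offspring", "mother", "group", "conc_start", "conc_end"),
            "offspring table")
  if (is.null(freqs)) freqs <- allele_frequencies(genotypes)
  cand_g <- setNames(lapply(candidates, get_genotypes, genotypes = genotypes),
                     candidates)
  cand_g <- cand_g[vapply(cand_g, length, integer(1L)) > 0L]
  out <- lapply(seq_len(nrow(offspring_tab)), function(i) {
    row <- offspring_tab[i, ]
    go <- get_genotypes(genotypes, row$offspring)
    gm <- get_genotypes(genotypes, row$mother)
    mat <- confirm_maternity(gm, go, min_maternity_loci)
    if (!mat$confirmed) {
      return(data.frame(offspring = row$offspring, sire = NA_character_,
                        category = "maternity_rejected", lod = NA_real_,
                        maternity_confirmed = FALSE,
                        n_candidates = length(cand_g),
                        stringsAsFactors = FALSE))
    }
    profs <- lapply(cand_g, function(cg) paternal_mismatches(gm, go, cg))
    pres <- vapply(names(cand_g), function(m) {
      any(memberships$id == m & memberships$group == row$group &
            memberships$entry <= row$conc_end &
            memberships$exit >= row$conc_start)
    }, logical(1L))
    asg <- assign_paternity(profs, pres)
    lod <- if (!is.na(asg$sire)) {
      lod_score(gm, go, cand_g[[asg$sire]], freqs, error_rate)
    } else NA_real_
    data.frame(offspring = row$offspring, sire = asg$sire,
               category = asg$category, lod = lod,
               maternity_confirmed = TRUE, n_candidates = length(cand_g),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
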