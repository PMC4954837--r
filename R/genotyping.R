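#' Consensus genotype from replicate PCRs (multi-tube rules)
#'
#' Applies the multiple-tube acceptance rules to the replicate reads of one
#' individual x locus:
#' \itemize{
#'   \item heterozygote accepted when two alleles are each confirmed in at
#'     least `min_het_reps` independent replicates and at least four
#'     replicates exist;
#'   \item homozygote accepted when a single allele is confirmed in at least
#'     `min_hom_reps` replicates while no second allele is ever confirmed
#'     twice (stray single-replicate alleles, e.g. one dropout-distorted or
#'     misprinted read among an extended run of replicates, do not block the
#'     call);
#'   \item anything else is unresolved (missing call);
#'   \item more than two alleles each confirmed twice is flagged as
#'     contamination (error).
#' }
#' Replicate order never matters; only per-allele confirmation counts do.
#'
#' @param replicates list of character vectors, one per replicate, each with
#'   1 or 2 allele labels.
#' @param min_het_reps confirmations required per allele for a heterozygote
#'   call (default 2).
#' @param min_hom_reps confirmations required for a homozygote call
#'   (default 6).
#' @return list with `call` (sorted pair of allele labels, or `NULL`),
#'   `status` (`"het_confirmed"`, `"hom_confirmed"` or `"unresolved"`) and
#'   `n_replicates`.
#' @export
call_consensus <- function(replicates, min_het_reps = 2L, min_hom_reps = 6L) {
  if (length(replicates) < 1L) stop_data("at least one replicate is required")
  seen <- unlist(lapply(replicates, unique))
  tab <- sort(table(seen), decreasing = TRUE)
  confirmed <- names(tab)[tab >= min_het_reps]
  n <- length(replicates)
  if (length(confirmed) > 2L) {
    stop_data("contamination: %d alleles (%s) each confirmed >= %d times",
              length(confirmed), paste(confirmed, collapse = ", "),
              min_het_reps)
  }
  if (length(confirmed) == 2L && n >= 4L) {
    return(list(call = sort(confirmed), status = "het_confirmed",
                n_replicates = n))
  }
  if (length(confirmed) == 1L && tab[[confirmed]] >= min_hom_reps) {
    return(list(call = c(confirmed, confirmed), status = "hom_confirmed",
                n_replicates = n))
  }
  list(call = NULL, status = "unresolved", n_replicates = n)
}

#' Call consensus genotypes for a whole replicate table
#'
#' @param replicates data frame with `individual`, `locus`, `replicate`,
#'   `allele1`, `allele2` (`allele2` `NA` for single-allele reads).
#' @inheritParams call_consensus
#' @param on_contamination `"error"` (default) aborts naming the offending
#'   individual x locus; `"unresolved"` records the cell as status
#'   `"contaminated"` with missing alleles and warns once.
#' @return data frame `individual`, `locus`, `allele1`, `allele2`, `status`;
#'   unresolved calls carry `NA` alleles.
#' @export
call_consensus_all <- function(replicates, min_het_reps = 2L,
                               min_hom_reps = 6L,
                               on_contamination = c("error", "unresolved")) {
  on_contamination <- match.arg(on_contamination)
  need_cols(replicates, c("individual", "locus", "allele1"), "PCR replicates")
  key <- paste(replicates$individual, replicates$locus, sep = "\r")
  idx <- split(seq_len(nrow(replicates)), key)
  out <- lapply(names(idx), function(k) {
    rows <- idx[[k]]
    reps <- lapply(rows, function(r) {
      a <- c(replicates$allele1[r], replicates$allele2[r])
      a[!is.na(a)]
    })
    res <- tryCatch(
      call_consensus(reps, min_het_reps, min_hom_reps),
      error = function(e) {
        if (on_contamination == "unresolved") {
          warning(sprintf("individual %s, locus %s: %s (set to missing)",
                          replicates$individual[rows[1L]],
                          replicates$locus[rows[1L]], conditionMessage(e)),
                  call. = FALSE)
          return(list(call = NULL, status = "contaminated"))
        }
        stop_data("individual %s, locus %s: %s",
                  replicates$individual[rows[1L]],
                  replicates$locus[rows[1L]], conditionMessage(e))
      })
    data.frame(individual = replicates$individual[rows[1L]],
               locus = replicates$locus[rows[1L]],
               allele1 = if (is.null(res$call)) NA_character_ else res$call[1L],
               allele2 = if (is.null(res$call)) NA_character_ else res$call[2L],
               status = res$status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$individual, res$locus), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-count allele frequencies per locus
#'
#' Each called individual contributes two allele copies. Unresolved calls
#' are ignored; loci without any call are excluded with a warning.
#'
#' @param genotypes data frame from [call_consensus_all()] (or with columns
#'   `individual`, `locus`, `allele1`, `allele2`).
#' @return data frame `locus`, `allele`, `freq` (summing to 1 per locus).
#' @export
allele_frequencies <- function(genotypes) {
  need_cols(genotypes, c("locus", "allele1", "allele2"), "genotypes")
  g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
  empty <- setdiff(unique(genotypes$locus), unique(g$locus))
  if (length(empty) > 0L) {
    warning(sprintf("locus/loci with zero called genotypes excluded: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(split(g, g$locus), function(d) {
    tab <- table(c(d$allele1, d$allele2))
    data.frame(locus = d$locus[1L], allele = names(tab),
               freq = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# PIC from a frequency vector: 1 - sum p_i^2 - sum_{i<j} 2 p_i^2 p_j^2.
pic_from_freqs <- function(p) {
  s2 <- sum(p^2)
  1 - s2 - (s2^2 - sum(p^4))
}

#' Per-locus summary statistics
#'
#' Observed heterozygosity (fraction of called individuals that are
#' heterozygous), number of alleles, expected heterozygosity
#' `He = 1 - sum(p^2)` (no small-sample correction), polymorphic information
#' content, the null-allele index `(He - Ho) / (He + Ho)`, and the one-locus
#' probabilities of identity ([pid_single()]).
#'
#' @inheritParams allele_frequencies
#' @return data frame with one row per called locus: `locus`, `n_typed`,
#'   `n_alleles`, `Ho`, `He`, `PIC`, `null_allele_index`, `PID`, `PIDsib`.
#' @export
locus_summary <- function(genotypes) {
  freqs <- allele_frequencies(genotypes)
  g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
  out <- lapply(split(g, g$locus), function(d) {
    p <- freqs$freq[freqs$locus == d$locus[1L]]
    ho <- mean(d$allele1 != d$allele2)
    he <- 1 - sum(p^2)
    ids <- pid_single(p)
    data.frame(locus = d$locus[1L], n_typed = nrow(d),
               n_alleles = length(p), Ho = ho, He = he,
               PIC = pic_from_freqs(p),
               null_allele_index = null_allele_index(ho, he),
               PID = ids[["pid"]], PIDsib = ids[["pidsib"]],
               stringsAsFactors = FALSE, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Null-allele index
#'
#' `(He - Ho) / (He + Ho)`: an excess of homozygotes relative to
#' Hardy-Weinberg expectation (positive values) flags a possible null
#' allele.
#'
#' @param ho observed heterozygosity.
#' @param he expected heterozygosity, in `(0, 1]`.
#' @return the index in `[-1, 1]`, or `NA` when `He` is 0.
#' @export
null_allele_index <- function(ho, he) {
  ifelse(he > 0, (he - ho) / (he + ho), NA_real_)
}

#' Monte Carlo exact test of Hardy-Weinberg equilibrium
#'
#' Chi-square statistic of observed versus HWE-expected genotype counts,
#' with the null distribution obtained by shuffling the 2n allele copies
#' among individuals and re-pairing them (a Monte Carlo exact test; the
#' asymptotic chi-square is unreliable for microsatellites with many rare
#' genotype classes). The observed allele configuration counts as one
#' permutation, so p lies in `(0, 1]`.
#'
#' @param genotypes data frame of calls at one locus (columns `allele1`,
#'   `allele2`), or a 2-column matrix of allele labels.
#' @param n_perm number of shuffles (>= 2000 recommended).
#' @param seed optional integer seed for reproducibility.
#' @return the Monte Carlo p-value; 1 for a monomorphic locus.
#' @export
hwe_test <- function(genotypes, n_perm = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(genotypes)) {
    g <- genotypes[!is.na(genotypes$allele1) & !is.na(genotypes$allele2), ]
    if ("locus" %in% names(g) && length(unique(g$locus)) > 1L) {
      stop_data("hwe_test expects genotypes from a single locus")
    }
    mat <- cbind(g$allele1, g$allele2)
  } else {
    mat <- genotypes
  }
  n <- nrow(mat)
  if (n < 5L) stop_data("hwe_test needs at least 5 called genotypes")
  alleles <- c(mat[, 1L], mat[, 2L])
  if (length(unique(alleles)) < 2L) return(1)

  stat <- hwe_chisq_stat(mat[, 1L], mat[, 2L], alleles)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    sh <- sample(alleles)
    s <- hwe_chisq_stat(sh[seq_len(n)], sh[n + seq_len(n)], alleles)
    if (s >= stat - 1e-12) hits <- hits + 1L
  }
  (1L + hits) / (1L + n_perm)
}

# Chi-square statistic of genotype counts against HWE expectations derived
# from the (fixed) allele counts.
hwe_chisq_stat <- function(a1, a2, alleles) {
  lev <- sort(unique(alleles))
  p <- as.numeric(table(factor(alleles, levels = lev))) / length(alleles)
  n <- length(a1)
  g1 <- pmin(a1, a2); g2 <- pmax(a1, a2)
  obs <- table(factor(paste(g1, g2), levels = genotype_levels(lev)))
  exp_p <- genotype_expected_probs(lev, p)
  e <- n * exp_p
  keep <- e > 0
  sum((as.numeric(obs)[keep] - e[keep])^2 / e[keep])
}

genotype_levels <- function(lev) {
  k <- length(lev)
  out <- character(k * (k + 1L) / 2L)
  idx <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    idx <- idx + 1L
    out[idx] <- paste(lev[i], lev[j])
  }
  out
}

genotype_expected_probs <- function(lev, p) {
  k <- length(lev)
  out <- numeric(k * (k + 1L) / 2L)
  idx <- 0L
  for (i in seq_len(k)) for (j in i:k) {
    idx <- idx + 1L
    out[idx] <- if (i == j) p[i]^2 else 2 * p[i] * p[j]
  }
  out
}

#' One-locus probabilities of identity
#'
#' `PID = 2 (sum p_i^2)^2 - sum p_i^4` is the probability that two unrelated
#' individuals share a genotype at the locus;
#' `PIDsib = 0.25 + 0.5 sum p_i^2 + 0.5 (sum p_i^2)^2 - 0.25 sum p_i^4` is
#' the conservative full-sibling version.
#'
#' @param p numeric vector of allele frequencies (summing to 1).
#' @return named numeric vector `c(pid = ..., pidsib = ...)`.
#' @export
pid_single <- function(p) {
  s2 <- sum(p^2); s4 <- sum(p^4)
  c(pid = 2 * s2^2 - s4,
    pidsib = 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4)
}

#' Multi-locus probabilities of identity
#'
#' Products of the per-locus values over the requested loci (independence
#' across loci assumed).
#'
#' @param freqs frequency table from [allele_frequencies()].
#' @param loci optional subset of loci (default: all).
#' @return list with `per_locus` (data frame `locus`, `PID`, `PIDsib`) and
#'   the multi-locus products `pid` and `pidsib`.
#' @export
pid_multi <- function(freqs, loci = NULL) {
  need_cols(freqs, c("locus", "allele", "freq"), "allele frequencies")
  if (is.null(loci)) loci <- unique(freqs$locus)
  per <- do.call(rbind, lapply(loci, function(l) {
    p <- freqs$freq[freqs$locus == l]
    if (length(p) == 0L) stop_data("no frequencies for locus %s", l)
    v <- pid_single(p)
    data.frame(locus = l, PID = v[["pid"]], PIDsib = v[["pidsib"]],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(per_locus = per, pid = prod(per$PID), pidsib = prod(per$PIDsib))
}

#' Minimum number of loci for reliable individual identification
#'
#' Smallest number of loci whose combined sibling probability of identity
#' drops to `threshold` or below, using the most informative (smallest
#' `PIDsib`) loci first.
#'
#' @inheritParams pid_multi
#' @param threshold target multi-locus `PIDsib` (e.g. 0.001).
#' @return list with `n_loci`, the achieved `pidsib_cumulative`, the locus
#'   order used (`loci`), and `attainable` (FALSE when even all loci do not
#'   reach the threshold; `n_loci` is then the total number of loci).
#' @export
min_loci_for_identity <- function(freqs, threshold = 0.001) {
  per <- pid_multi(freqs)$per_locus
  per <- per[order(per$PIDsib), , drop = FALSE]
  cum <- cumprod(per$PIDsib)
  k <- which(cum <= threshold)
  if (length(k) == 0L) {
    list(n_loci = nrow(per), pidsib_cumulative = cum[nrow(per)],
         loci = per$locus, attainable = FALSE)
  } else {
    k <- k[1L]
    list(n_loci = k, pidsib_cumulative = cum[k], loci = per$locus[seq_len(k)],
         attainable = TRUE)
  }
}
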