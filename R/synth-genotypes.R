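#' Simulate replicate microsatellite PCR calls
#'
#' Founder (adult) genotypes are drawn from per-locus allele frequencies
#' (Dirichlet(1,...,1) by default); infants inherit one maternal and one
#' paternal allele. Each PCR replicate of a heterozygote independently drops
#' each allele with `dropout_rate` (if both drop, one allele is still read,
#' chosen at random, emulating a false homozygote), and every shown allele is
#' substituted by a random allele of the locus with `misprint_rate`.
#'
#' @param pop a [simulate_population()] result.
#' @param cfg a [sim_config()]; defaults to the one stored in `pop`.
#' @param allele_freqs optional list of per-locus numeric frequency vectors
#'   (overrides the Dirichlet draw; names become allele labels).
#' @return a list of class `sim_genotypes`:
#'   \describe{
#'     \item{replicates}{`individual`, `locus`, `replicate`, `allele1`,
#'       `allele2` (`NA` when only one allele was read).}
#'     \item{truth}{true genotypes: `individual`, `locus`, `allele1`,
#'       `allele2`.}
#'     \item{freqs}{generating allele frequencies: `locus`, `allele`,
#'       `freq`.}
#'   }
#' @export
simulate_genotypes <- function(pop, cfg = pop$config, allele_freqs = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(cfg$seed + 3L)
  roster <- pop$roster
  loci <- sprintf("L%02d", seq_len(cfg$msat_loci))

  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  for (l in loci) {
    if (!is.null(allele_freqs)) {
      p <- allele_freqs[[l]] %||% allele_freqs[[match(l, loci)]]
      if (is.null(names(p))) {
        names(p) <- sprintf("%d", 100L + 4L * seq_along(p))
      }
    } else {
      g <- rgamma(cfg$alleles_per_locus, 1)
      p <- setNames(g / sum(g), sprintf("%d", 100L + 4L * seq_len(cfg$alleles_per_locus)))
    }
    freqs[[l]] <- p
  }

  adults <- roster$id[roster$class %in% c("adult_female", "adult_male")]
  infants <- roster[roster$class == "infant", , drop = FALSE]

  # true genotypes: HWE founders, Mendelian offspring
  geno <- new.env(parent = emptyenv())
  for (id in adults) {
    geno[[id]] <- vapply(loci, function(l) {
      p <- freqs[[l]]
      sample(names(p), 2L, replace = TRUE, prob = p)
    }, character(2L))
  }
  for (i in seq_len(nrow(infants))) {
    gm <- geno[[infants$mother[i]]]
    gf <- geno[[infants$sire[i]]]
    geno[[infants$id[i]]] <- vapply(seq_along(loci), function(j) {
      c(gm[sample.int(2L, 1L), j], gf[sample.int(2L, 1L), j])
    }, character(2L))
    colnames(geno[[infants$id[i]]]) <- loci
  }

  ids <- c(adults, infants$id)
  truth <- do.call(rbind, lapply(ids, function(id) {
    g <- geno[[id]]
    data.frame(individual = id, locus = loci,
               allele1 = pmin(g[1L, ], g[2L, ]),
               allele2 = pmax(g[1L, ], g[2L, ]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  # replicate PCRs with dropout + misprint
  reps <- vector("list", length(ids) * length(loci))
  k <- 0L
  for (id in ids) {
    g <- geno[[id]]
    for (l in loci) {
      tg <- g[, l]
      k <- k + 1L
      calls <- lapply(seq_len(cfg$pcr_replicates), function(r) {
        pcr_replicate_call(tg, freqs[[l]], cfg$dropout_rate, cfg$misprint_rate)
      })
      reps[[k]] <- data.frame(
        individual = id, locus = l, replicate = seq_len(cfg$pcr_replicates),
        allele1 = vapply(calls, `[`, character(1L), 1L),
        allele2 = vapply(calls, function(x) {
          if (length(x) > 1L) x[2L] else NA_character_
        }, character(1L)),
        stringsAsFactors = FALSE)
    }
  }
  replicates <- do.call(rbind, reps)
  rownames(replicates) <- NULL

  freq_df <- do.call(rbind, lapply(loci, function(l) {
    data.frame(locus = l, allele = names(freqs[[l]]),
               freq = as.numeric(freqs[[l]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  structure(list(replicates = replicates, truth = truth, freqs = freq_df),
            class = "sim_genotypes")
}

# One PCR read of a true genotype: sorted character vector of 1 or 2 alleles.
pcr_replicate_call <- function(true_pair, freq, dropout, misprint) {
  a <- true_pair
  if (a[1L] != a[2L]) {
    keep <- runif(2L) >= dropout
    shown <- unique(a[keep])
    if (length(shown) == 0L) shown <- a[sample.int(2L, 1L)]
  } else {
    shown <- a[1L]
  }
  flip <- runif(length(shown)) < misprint
  if (any(flip)) {
    shown[flip] <- sample(names(freq), sum(flip), replace = TRUE)
    shown <- unique(shown)
  }
  sort(shown)
}

#' Run all generator stages under one configuration
#'
#' Convenience wrapper producing a complete synthetic dataset (population,
#' agonistic events, focal data, genotypes). Each stage seeds its own RNG
#' stream from `cfg$seed`, so identical configurations give byte-identical
#' datasets.
#'
#' @param cfg a [sim_config()].
#' @return a list with elements `population`, `agonistic`, `focal`,
#'   `genotypes`, and `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  pop <- simulate_population(cfg)
  list(population = pop,
       agonistic = simulate_agonistic(pop, cfg),
       focal = simulate_focal_data(pop, cfg),
       genotypes = simulate_genotypes(pop, cfg),
       config = cfg)
}
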