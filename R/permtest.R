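#' Dyadic affiliation contingency table
#'
#' Counts affiliative interactions per (initiator, recipient) pair for one
#' group and direction. Adult males are retained only when resident for the
#' entire study period (immigrants/emigrants are dropped with all their
#' events); focal infants are always retained.
#'
#' @param events interaction events (`day`, `group`, `initiator`,
#'   `recipient`, `behavior`).
#' @param roster roster with `id`, `class`.
#' @param memberships membership intervals.
#' @param group group id to tabulate.
#' @param direction `"infant_to_male"` or `"male_to_infant"`.
#' @param period length-2 integer vector, the full study period against
#'   which male presence is checked.
#' @param behaviors behaviors counted as affiliative.
#' @return list of class `dyad_table`: `tab` (counts matrix,
#'   initiators x recipients), `group`, `direction`, `n` (total events).
#' @export
build_dyad_table <- function(events, roster, memberships, group,
                             direction = c("infant_to_male", "male_to_infant"),
                             period,
                             behaviors = c("approach", "groom", "friendly")) {
  direction <- match.arg(direction)
  need_cols(events, c("day", "group", "initiator", "recipient", "behavior"),
            "interaction events")
  ev <- events[events$group == group & events$behavior %in% behaviors, ]
  cls <- setNames(roster$class, roster$id)
  init_cls <- if (direction == "infant_to_male") "infant" else "adult_male"
  ev <- ev[cls[ev$initiator] %in% init_cls, , drop = FALSE]

  # full-presence filter on adult males
  full <- memberships$id[memberships$group == group &
                           memberships$entry <= period[1L] &
                           memberships$exit >= period[2L]]
  male_col <- if (direction == "infant_to_male") "recipient" else "initiator"
  males <- unique(ev[[male_col]])
  keep_males <- males[males %in% full]
  ev <- ev[ev[[male_col]] %in% keep_males, , drop = FALSE]
  if (nrow(ev) == 0L) {
    stop_data("no events remain for group %s (%s) after the full-presence filter",
              group, direction)
  }
  tab <- table(initiator = factor(ev$initiator),
               recipient = factor(ev$recipient))
  structure(list(tab = unclass(as.matrix(tab)), group = group,
                 direction = direction, n = nrow(ev)),
            class = "dyad_table")
}

#' Chi-square statistic of a dyadic contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the row/column marginals.
#' Rows and columns without any event are dropped first (their expectations
#' are zero). The table must retain at least two rows and two columns.
#'
#' @param tab counts matrix, or a `dyad_table`.
#' @return the chi-square statistic (0 iff observed equals expected
#'   everywhere).
#' @export
chi_square_stat <- function(tab) {
  if (inherits(tab, "dyad_table")) tab <- tab$tab
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_data("degenerate table: need >= 2 non-empty rows and columns")
  }
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - e)^2 / e)
}

#' Permutation test for non-random dyadic partner preference
#'
#' Shuffles the initiator labels across events (preserving every
#' initiator's total and every recipient's total), recomputes the
#' chi-square statistic of the dyadic contingency table for each
#' permutation, and reports the upper-tail p-value with the original data
#' counted as one permutation: `p = #(chi2_perm >= chi2_obs) / n_perm`.
#' Chi-square is non-directional, so this upper-tail count is the two-sided
#' test.
#'
#' @param events data frame with `initiator` and `recipient` columns
#'   (already filtered to one group/direction, e.g. the events behind a
#'   [build_dyad_table()]).
#' @param n_perm number of permutations including the original (default
#'   10000; fewer than 100 triggers a warning).
#' @param seed optional integer seed.
#' @return object of class `dyad_permtest`: `statistic`, `p_value`,
#'   `n_perm`, `tab` (observed counts), `expected`, `adj_residuals`
#'   (adjusted standardized residuals), `perm_stats`.
#' @export
permutation_test <- function(events, n_perm = 10000L, seed = NULL) {
  need_cols(events, c("initiator", "recipient"), "events")
  if (n_perm < 100L) {
    warning("fewer than 100 permutations gives a very coarse p-value",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  init <- factor(events$initiator)
  rec <- factor(events$recipient)
  if (nlevels(init) < 2L || nlevels(rec) < 2L) {
    stop_data("degenerate data: need >= 2 distinct initiators and recipients")
  }
  nr <- nlevels(init); nc <- nlevels(rec)
  ri <- as.integer(init); ci <- as.integer(rec)
  obs <- tabulate(ri + nr * (ci - 1L), nbins = nr * nc)
  obs_m <- matrix(obs, nr, nc, dimnames = list(levels(init), levels(rec)))
  stat_of <- function(counts) {
    m <- matrix(counts, nr, nc)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    n <- sum(m)
    e <- outer(rowSums(m), colSums(m)) / n
    sum((m - e)^2 / e)
  }
  stat_obs <- stat_of(obs)
  stats <- numeric(n_perm)
  stats[1L] <- stat_obs  # the original data is one permutation
  for (b in seq_len(n_perm - 1L)) {
    rp <- sample(ri)
    stats[b + 1L] <- stat_of(tabulate(rp + nr * (ci - 1L), nbins = nr * nc))
  }
  p <- mean(stats >= stat_obs - 1e-12)

  n <- sum(obs_m)
  e <- outer(rowSums(obs_m), colSums(obs_m)) / n
  rp_ <- rowSums(obs_m) / n
  cp_ <- colSums(obs_m) / n
  denom <- sqrt(e * outer(1 - rp_, 1 - cp_))
  adj <- (obs_m - e) / denom
  adj[!is.finite(adj)] <- 0
  structure(list(statistic = stat_obs, p_value = p, n_perm = n_perm,
                 tab = obs_m, expected = e, adj_residuals = adj,
                 perm_stats = stats),
            class = "dyad_permtest")
}

#' @export
print.dyad_permtest <- function(x, ...) {
  cat(sprintf("Dyadic permutation test: chi2 = %.1f, N = %d, p = %.4g (%d permutations)\n",
              x$statistic, sum(x$tab), x$p_value, x$n_perm))
  invisible(x)
}

#' Preferred-partner flags from adjusted residuals
#'
#' Flags a dyad as a preferred partnership when its adjusted standardized
#' residual `(O - E) / sqrt(E (1 - row_prop) (1 - col_prop))` exceeds
#' `z_crit` (default 1.96). Meaningful only when the permutation test
#' itself rejected randomness.
#'
#' @param ptres a [permutation_test()] result.
#' @param z_crit residual threshold (default 1.96).
#' @return list with `pairs` (data frame `initiator`, `recipient`,
#'   `observed`, `expected`, `adj_residual`, `preferred`) and
#'   `per_initiator` (named count of preferred partners per initiator).
#' @export
preferred_partners <- function(ptres, z_crit = 1.96) {
  stopifnot(inherits(ptres, "dyad_permtest"))
  tab <- ptres$tab
  df <- data.frame(
    initiator = rep(rownames(tab), ncol(tab)),
    recipient = rep(colnames(tab), each = nrow(tab)),
    observed = as.vector(tab),
    expected = as.vector(ptres$expected),
    adj_residual = as.vector(ptres$adj_residuals),
    stringsAsFactors = FALSE)
  df$preferred <- df$adj_residual > z_crit
  counts <- tapply(df$preferred, df$initiator, sum)
  list(pairs = df, per_initiator = counts[rownames(tab)])
}

# Exact permutation p-value by enumeration of all distinct initiator-label
# orderings; practical only for small event lists (used as a test oracle
# and for verification on tiny tables).
permutation_test_exact <- function(events) {
  init <- factor(events$initiator)
  rec <- factor(events$recipient)
  nr <- nlevels(init); nc <- nlevels(rec)
  ri <- as.integer(init); ci <- as.integer(rec)
  n <- length(ri)
  if (n > 9L) stop_data("exact enumeration supported for <= 9 events")
  stat_of <- function(r) {
    m <- matrix(tabulate(r + nr * (ci - 1L), nbins = nr * nc), nr, nc)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  perms <- all_permutations(n)
  stats <- apply(perms, 1L, function(ix) stat_of(ri[ix]))
  obs <- stat_of(ri)
  mean(stats >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}
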