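#' Simulate dated agonistic events
#'
#' Draws decided dyadic agonistic events (displacements / aggression with a
#' clear winner) among co-resident same-sex adults. Event counts per
#' group-day are Poisson; the winner is decided by a logistic function of the
#' latent-strength difference, so realized dominance reflects strength up to
#' sampling noise.
#'
#' @param pop a [simulate_population()] result.
#' @param cfg a [sim_config()]; defaults to the one stored in `pop`.
#' @return data frame with `day`, `group`, `winner`, `loser`.
#' @export
simulate_agonistic <- function(pop, cfg = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(cfg$seed + 1L)
  roster <- pop$roster
  adults <- roster[roster$class %in% c("adult_female", "adult_male"), ]
  memb <- pop$memberships[pop$memberships$id %in% adults$id, ]
  strength <- setNames(adults$strength, adults$id)
  sex <- setNames(adults$sex, adults$id)

  out <- vector("list", cfg$n_groups)
  gi <- 0L
  for (g in paste0("G", seq_len(cfg$n_groups))) {
    gi <- gi + 1L
    gm <- memb[memb$group == g, ]
    n_events <- rpois(cfg$study_days, cfg$agonistic_per_group_day)
    total <- sum(n_events)
    day_v <- rep.int(seq_len(cfg$study_days), n_events)
    win <- lose <- character(total)
    dday <- integer(total)
    k <- 0L
    for (d in unique(day_v)) {
      ids <- gm$id[gm$entry <= d & gm$exit >= d]
      sx <- sex[ids]
      n_f <- sum(sx == "F"); n_m <- sum(sx == "M")
      w_f <- n_f * (n_f - 1); w_m <- n_m * (n_m - 1)
      if (w_f + w_m == 0) next
      for (e in seq_len(sum(day_v == d))) {
        s <- if (runif(1) < w_f / (w_f + w_m)) "F" else "M"
        pair <- sample(ids[sx == s], 2L)
        p1 <- plogis((strength[pair[1L]] - strength[pair[2L]]) /
                       cfg$contest_scale)
        k <- k + 1L
        dday[k] <- d
        if (runif(1) < p1) {
          win[k] <- pair[1L]; lose[k] <- pair[2L]
        } else {
          win[k] <- pair[2L]; lose[k] <- pair[1L]
        }
      }
    }
    if (k > 0L) {
      out[[gi]] <- data.frame(day = dday[seq_len(k)], group = g,
                              winner = win[seq_len(k)],
                              loser = lose[seq_len(k)],
                              stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  ev <- ev[order(ev$day), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
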