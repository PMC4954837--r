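#' Elo rating configuration
#'
#' Update constants for the sequential Elo dominance rating. The defaults
#' (start 1000, k 100, base-10 logistic expectation with scale 400) are the
#' conventional constants of the standard Elo implementation for animal
#' dominance data; all three are configurable.
#'
#' @param start_rating rating assigned to every individual on entry.
#' @param k_factor maximum rating change per interaction (k > 0).
#' @param logistic_scale scale of the base-10 logistic expectation (> 0).
#' @return a list of class `elo_config`.
#' @export
elo_config <- function(start_rating = 1000, k_factor = 100,
                       logistic_scale = 400) {
  if (k_factor <= 0) stop_data("k_factor must be > 0")
  if (logistic_scale <= 0) stop_data("logistic_scale must be > 0")
  structure(list(start_rating = start_rating, k_factor = k_factor,
                 logistic_scale = logistic_scale), class = "elo_config")
}

#' Expected score of an Elo contest
#'
#' Probability that the first contestant wins,
#' `1 / (1 + 10^((r_b - r_a) / scale))`. Symmetric:
#' `elo_expected(a, b) + elo_expected(b, a) == 1`.
#'
#' @param r_a,r_b ratings of the two contestants (vectorized).
#' @param logistic_scale logistic scale (default 400).
#' @return win probability of the first contestant.
#' @export
elo_expected <- function(r_a, r_b, logistic_scale = 400) {
  1 / (1 + 10^((r_b - r_a) / logistic_scale))
}

#' Sequential Elo update over dated agonistic events
#'
#' Processes events in date order (ties broken by input order). The winner
#' gains `k * (1 - p_win)` points and the loser loses the same amount, so
#' total rating mass is conserved. Individuals enter at `start_rating` on
#' first appearance.
#'
#' @param events data frame with `day`, `winner`, `loser` (and `group` if
#'   residence is to be validated).
#' @param memberships optional membership table (`id`, `group`, `entry`,
#'   `exit`); when provided, every contestant must be resident in the
#'   event's group on the event day, otherwise an error lists the offending
#'   rows.
#' @param config an [elo_config()].
#' @return an object of class `elo_timeline`: list with `events` (the input
#'   plus pre/post ratings of both contestants), `final` (named vector of
#'   final ratings) and `config`.
#' @export
elo_update <- function(events, memberships = NULL, config = elo_config()) {
  need_cols(events, c("day", "winner", "loser"), "agonistic events")
  if (!is.null(memberships)) {
    need_cols(events, "group", "agonistic events")
    known <- unique(memberships$id)
    bad_id <- !(events$winner %in% known) | !(events$loser %in% known)
    if (any(bad_id)) {
      stop_data("agonistic events reference unknown individual(s) in row(s): %s",
                paste(utils::head(which(bad_id), 10L), collapse = ", "))
    }
    ok <- is_resident(memberships, events$winner, events$day, events$group) &
      is_resident(memberships, events$loser, events$day, events$group)
    if (any(!ok)) {
      stop_data("contestants not co-resident in the stated group in row(s): %s",
                paste(utils::head(which(!ok), 10L), collapse = ", "))
    }
  }
  ord <- order(events$day)  # stable: ties keep input order
  ev <- events[ord, , drop = FALSE]
  n <- nrow(ev)
  ratings <- new.env(parent = emptyenv())
  get_r <- function(id) {
    if (is.null(ratings[[id]])) config$start_rating else ratings[[id]]
  }
  pre_w <- pre_l <- post_w <- post_l <- numeric(n)
  for (i in seq_len(n)) {
    rw <- get_r(ev$winner[i]); rl <- get_r(ev$loser[i])
    p <- elo_expected(rw, rl, config$logistic_scale)
    delta <- config$k_factor * (1 - p)
    pre_w[i] <- rw; pre_l[i] <- rl
    post_w[i] <- rw + delta; post_l[i] <- rl - delta
    ratings[[ev$winner[i]]] <- post_w[i]
    ratings[[ev$loser[i]]] <- post_l[i]
  }
  ev$pre_winner <- pre_w; ev$pre_loser <- pre_l
  ev$post_winner <- post_w; ev$post_loser <- post_l
  ids <- ls(ratings)
  structure(list(events = ev,
                 final = setNames(vapply(ids, get_r, numeric(1L)), ids),
                 config = config),
            class = "elo_timeline")
}

#' Daily Elo ratings for all resident adults
#'
#' Expands an [elo_update()] timeline to one row per resident adult per
#' study day. An individual's rating changes only on its event days;
#' individuals carry `start_rating` from their entry until their first
#' event. Ratings are defined only on days within an individual's residence.
#'
#' @param timeline an `elo_timeline`.
#' @param roster roster with `id`, `sex`, `class`.
#' @param memberships membership intervals (`id`, `group`, `entry`, `exit`).
#' @param days integer vector of study days to cover (default: full span of
#'   the membership table).
#' @return data frame with `id`, `day`, `group`, `sex`, `rating`.
#' @export
elo_daily <- function(timeline, roster, memberships, days = NULL) {
  stopifnot(inherits(timeline, "elo_timeline"))
  adults <- roster[roster$class %in% c("adult_female", "adult_male"), ]
  memb <- memberships[memberships$id %in% adults$id, , drop = FALSE]
  if (is.null(days)) days <- seq.int(min(memb$entry), max(memb$exit))
  ev <- timeline$events
  out <- vector("list", nrow(memb))
  for (j in seq_len(nrow(memb))) {
    id <- memb$id[j]
    dd <- days[days >= memb$entry[j] & days <= memb$exit[j]]
    if (length(dd) == 0L) next
    ei <- ev[ev$winner == id | ev$loser == id, , drop = FALSE]
    if (nrow(ei) > 0L) {
      post <- ifelse(ei$winner == id, ei$post_winner, ei$post_loser)
      idx <- findInterval(dd, ei$day)
      rating <- ifelse(idx == 0L, timeline$config$start_rating, post[pmax(idx, 1L)])
    } else {
      rating <- rep(timeline$config$start_rating, length(dd))
    }
    out[[j]] <- data.frame(id = id, day = dd, group = memb$group[j],
                           sex = adults$sex[match(id, adults$id)],
                           rating = rating, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Standardize daily Elo ratings within sex and group
#'
#' On each (group, sex, day) stratum, maps raw ratings affinely to `[0, 1]`:
#' `(r - min) / (max - min)`, so the lowest-rated individual scores 0 and the
#' highest 1. Degenerate strata (a single individual, or all ratings equal)
#' score 0.5, the midpoint, to avoid spurious extreme ranks.
#'
#' @param daily a data frame from [elo_daily()] (`id`, `day`, `group`,
#'   `sex`, `rating`).
#' @return the input with an added `rank_std` column in `[0, 1]`.
#' @export
elo_standardize <- function(daily) {
  need_cols(daily, c("id", "day", "group", "sex", "rating"), "daily ratings")
  key <- paste(daily$group, daily$sex, daily$day, sep = "\r")
  lo <- ave(daily$rating, key, FUN = min)
  hi <- ave(daily$rating, key, FUN = max)
  daily$rank_std <- ifelse(hi > lo, (daily$rating - lo) / (hi - lo), 0.5)
  daily
}
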