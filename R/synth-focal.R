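#' Simulate focal-follow scan and interaction data
#'
#' For every infant-day in the focal window (birth to weaning age) the
#' generator draws an observation effort (scans), mother / male proximity
#' scan counts, mother-male co-presence and affiliation counts, and the
#' dyadic affiliation events themselves. The daily log-odds that a dyad
#' affiliates, separately for the infant-initiated and the male-initiated
#' direction, is the configured `true_effects` linear predictor evaluated on
#' the z-scored analysis predictors (exactly the transforms
#' [assemble_model_table()] later applies) plus a per-dyad AR(1) latent term,
#' so downstream model fits have known truth to recover and the
#' autocorrelation machinery has real signal to detect.
#'
#' @param pop a [simulate_population()] result.
#' @param cfg a [sim_config()]; defaults to the one stored in `pop`.
#' @return a list of class `sim_focal`:
#'   \describe{
#'     \item{scans_daily}{`infant`, `day`, `group`, `obs_scans`,
#'       `mother_scans` (scans with the mother within 2.5 m).}
#'     \item{prox_daily}{dyad-day proximity counts: `infant`, `male`, `day`,
#'       `group`, `male_scans`, `mm_scans` (mother and male co-present),
#'       `mm_affil` (co-presence scans with a mother-male affiliation).}
#'     \item{interactions}{dated events: `day`, `group`, `initiator`,
#'       `recipient`, `behavior` (`approach`/`groom`/`friendly`/`aggression`).}
#'     \item{truth}{the generating dyad-day table with the z-scored
#'       predictors, AR(1) values and both binary responses; see
#'       [truth_model_table()].}
#'   }
#' @export
simulate_focal_data <- function(pop, cfg = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(cfg$seed + 2L)
  roster <- pop$roster
  memb <- pop$memberships
  infants <- roster[roster$class == "infant", , drop = FALSE]
  if (nrow(infants) == 0L) {
    stop_data("population contains no infants; increase birth_rate or study_days")
  }

  # --- observation effort and mother proximity per infant-day -------------
  sc <- list()
  for (i in seq_len(nrow(infants))) {
    inf <- infants[i, ]
    d0 <- inf$birth_day
    d1 <- min(inf$birth_day + cfg$focal_age_days - 1L, cfg$study_days)
    days <- seq.int(d0, d1)
    n <- length(days)
    follows <- pmax(1L, rpois(n, cfg$follows_per_day_mean))
    obs <- cfg$scans_per_follow * follows
    sc[[i]] <- data.frame(infant = inf$id, day = days, group = inf$group,
                          obs_scans = obs,
                          mother_scans = rbinom(n, obs, cfg$p_mother_near),
                          stringsAsFactors = FALSE)
  }
  scans_daily <- do.call(rbind, sc)

  # --- male rank (rank-standardized latent strength) per group-day --------
  males <- roster[roster$class == "adult_male", , drop = FALSE]
  strength <- setNames(males$strength, males$id)
  rank_env <- male_rank_by_day(memb[memb$id %in% males$id, ], strength,
                               cfg$study_days)
  fem <- roster[roster$class == "adult_female", , drop = FALSE]
  mother_rank_of <- unlist(lapply(split(fem, fem$group), function(d) {
    n <- nrow(d)
    r <- if (n > 1L) (rank(d$strength) - 1) / (n - 1) else rep(0.5, n)
    setNames(r, d$id)
  }))
  names(mother_rank_of) <- sub("^G\\d+\\.", "", names(mother_rank_of))

  # --- dyad-day grid -------------------------------------------------------
  mmemb <- memb[memb$id %in% males$id, , drop = FALSE]
  dyads <- list()
  for (i in seq_len(nrow(infants))) {
    inf <- infants[i, ]
    s_i <- scans_daily[scans_daily$infant == inf$id, ]
    spells <- mmemb[mmemb$group == inf$group, , drop = FALSE]
    for (j in seq_len(nrow(spells))) {
      lo <- max(min(s_i$day), spells$entry[j])
      hi <- min(max(s_i$day), spells$exit[j])
      if (lo > hi) next
      days <- seq.int(lo, hi)
      dyads[[length(dyads) + 1L]] <- data.frame(
        infant = inf$id, male = spells$id[j], group = inf$group, day = days,
        male_entry = spells$entry[j], stringsAsFactors = FALSE)
    }
  }
  dd <- do.call(rbind, dyads)
  dd <- dd[order(dd$infant, dd$male, dd$day), , drop = FALSE]
  rownames(dd) <- NULL
  key <- match(paste(dd$infant, dd$day), paste(scans_daily$infant, scans_daily$day))
  dd$obs_scans <- scans_daily$obs_scans[key]
  dd$mother_scans <- scans_daily$mother_scans[key]
  n <- nrow(dd)

  # proximity and mother-male affiliation counts
  dd$male_scans <- rbinom(n, dd$obs_scans, cfg$p_male_near)
  # mother within 2.5 m on a scan independently of the male, so co-presence
  # is binomial within the male-proximity scans
  dd$mm_scans <- pmin(rbinom(n, dd$male_scans, cfg$p_mother_near),
                      dd$mother_scans)
  dd$mother <- infants$mother[match(dd$infant, infants$id)]
  pair <- paste(dd$mother, dd$male)
  upair <- unique(pair)
  bond_p <- setNames(rbeta(length(upair), cfg$bond_shape1, cfg$bond_shape2),
                     upair)
  dd$mm_affil <- rbinom(n, dd$mm_scans, bond_p[pair])

  # --- analysis-scale predictors (generated, then z-scored as the model
  # table will z-score them) ----------------------------------------------
  dd$male_rank_raw <- mapply(function(id, day) rank_env[[id]][day],
                             dd$male, dd$day)
  dd$mother_rank_raw <- mother_rank_of[dd$mother]
  dyad_key <- paste(dd$infant, dd$male)
  cum_aff <- ave(dd$mm_affil, dyad_key, FUN = cumsum)
  cum_cop <- ave(dd$mm_scans, dyad_key, FUN = cumsum)
  dd$bond_raw <- ifelse(cum_cop > 0, cum_aff / cum_cop, 0)
  dd$paternity <- as.integer(infants$sire[match(dd$infant, infants$id)] == dd$male)
  conc <- infants[match(dd$infant, infants$id), c("conc_start", "conc_end")]
  dd$present_at_conception <- as.integer(mapply(function(m, g, cs, ce) {
    any(mmemb$id == m & mmemb$group == g & mmemb$entry <= ce & mmemb$exit >= cs)
  }, dd$male, dd$group, conc$conc_start, conc$conc_end))

  dd$male_rank <- z_center(dd$male_rank_raw)
  dd$mother_rank <- z_center(dd$mother_rank_raw)
  dd$mother_presence <- z_center(log1p(dd$mother_scans))
  dd$mother_male_affiliation <- z_center(dd$bond_raw)


  # control covariates carried in the truth table (no generative effect)
  dd$infant_sex <- infants$sex[match(dd$infant, infants$id)]
  birth <- infants$birth_day[match(dd$infant, infants$id)]
  dd$infant_age <- z_center(dd$day - birth)
  nm_env <- males_present_by_day(mmemb, cfg$study_days)
  dd$n_males <- z_center(mapply(function(g, d) nm_env[[g]][d],
                                  dd$group, dd$day))
  doy <- day_of_year(dd$day, cfg$origin_date)
  dd$season_sin <- sin(2 * pi * doy / 365.25)
  dd$season_cos <- cos(2 * pi * doy / 365.25)
  dd$male_tenure <- z_center(dd$day - dd$male_entry)
  dd$dyad <- dyad_key

  # --- per-dyad AR(1) latent term on the logit scale ----------------------
  dd$ar <- ar1_by_group(dyad_key, cfg$ar1_rho, cfg$ar1_sd)

  # observation effort enters the generating odds as a centred log offset,
  # matching the offset(log(obs_scans)) term of the fitted models; the
  # configured intercepts refer to a day of average (geometric-mean) effort
  effort <- log(dd$obs_scans) - mean(log(dd$obs_scans))
  te <- cfg$true_effects
  # generic linear predictor over (possibly interaction) term names:
  # "a:b" contributes beta * a * b on the z-scored columns
  term_value <- function(nm) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1L]]
    Reduce(`*`, lapply(parts, function(p) dd[[p]]))
  }
  eta_of <- function(direction) {
    eta <- dd$ar + effort
    for (nm in names(te)) {
      if (direction == "infant" &&
          any(grepl("present_at_conception",
                    strsplit(nm, ":", fixed = TRUE)[[1L]], fixed = TRUE))) {
        next  # conception presence acts on the male direction only
      }
      eta <- eta + te[[nm]] * term_value(nm)
    }
    eta
  }
  dd$response_infant <- rbinom(n, 1L, plogis(cfg$intercept_infant +
                                               eta_of("infant")))
  dd$response_male <- rbinom(n, 1L, plogis(cfg$intercept_male +
                                             eta_of("male")))

  # --- event records -------------------------------------------------------
  interactions <- emit_events(dd, cfg)

  drop <- c("male_entry")
  truth <- dd[, setdiff(names(dd), drop)]
  structure(list(scans_daily = scans_daily,
                 prox_daily = dd[, c("infant", "male", "day", "group",
                                     "male_scans", "mm_scans", "mm_affil")],
                 interactions = interactions,
                 truth = truth),
            class = "sim_focal")
}

# Per-male vector over days of rank-standardized strength among the males
# co-resident in the same group (0 = lowest, 1 = highest, 0.5 if alone).
male_rank_by_day <- function(mmemb, strength, study_days) {
  env <- new.env(parent = emptyenv())
  for (id in unique(mmemb$id)) {
    env[[id]] <- rep(NA_real_, study_days)
  }
  for (g in unique(mmemb$group)) {
    gm <- mmemb[mmemb$group == g, , drop = FALSE]
    bps <- sort(unique(c(1L, gm$entry, gm$exit + 1L, study_days + 1L)))
    bps <- bps[bps >= 1L & bps <= study_days + 1L]
    for (k in seq_len(length(bps) - 1L)) {
      lo <- bps[k]; hi <- bps[k + 1L] - 1L
      ids <- gm$id[gm$entry <= lo & gm$exit >= hi]
      if (length(ids) == 0L) next
      r <- if (length(ids) > 1L) {
        (rank(strength[ids]) - 1) / (length(ids) - 1)
      } else 0.5
      for (i in seq_along(ids)) env[[ids[i]]][lo:hi] <- r[i]
    }
  }
  env
}

# Number of resident adult males per group-day.
males_present_by_day <- function(mmemb, study_days) {
  env <- new.env(parent = emptyenv())
  for (g in unique(mmemb$group)) {
    v <- integer(study_days)
    gm <- mmemb[mmemb$group == g, , drop = FALSE]
    for (j in seq_len(nrow(gm))) {
      lo <- max(1L, gm$entry[j]); hi <- min(study_days, gm$exit[j])
      if (lo <= hi) v[lo:hi] <- v[lo:hi] + 1L
    }
    env[[g]] <- v
  }
  env
}

# Stationary AR(1) stream per contiguous run of each grouping key.
ar1_by_group <- function(key, rho, sd_stat) {
  n <- length(key)
  if (sd_stat == 0) return(numeric(n))
  out <- numeric(n)
  idx <- split(seq_len(n), key)
  innov_sd <- sd_stat * sqrt(1 - rho^2)
  for (ix in idx) {
    m <- length(ix)
    z <- numeric(m)
    z[1L] <- rnorm(1L, 0, sd_stat)
    if (m > 1L) {
      e <- rnorm(m - 1L, 0, innov_sd)
      for (t in 2:m) z[t] <- rho * z[t - 1L] + e[t - 1L]
    }
    out[ix] <- z
  }
  out
}

# Turn positive dyad-day responses into dated interaction events, plus a
# trickle of male-to-infant aggression for the descriptive ratios.
emit_events <- function(dd, cfg) {
  beh <- c("approach", "groom", "friendly")
  pr <- c(0.92, 0.03, 0.05)
  rows <- list()
  mk <- function(sel, init, recip) {
    m <- sum(sel)
    if (m == 0L) return(NULL)
    n_ev <- 1L + rpois(m, cfg$extra_events_mean)
    data.frame(day = rep.int(dd$day[sel], n_ev),
               group = rep.int(dd$group[sel], n_ev),
               initiator = rep.int(init[sel], n_ev),
               recipient = rep.int(recip[sel], n_ev),
               behavior = sample(beh, sum(n_ev), replace = TRUE, prob = pr),
               stringsAsFactors = FALSE)
  }
  rows[[1L]] <- mk(dd$response_infant == 1L, dd$infant, dd$male)
  rows[[2L]] <- mk(dd$response_male == 1L, dd$male, dd$infant)
  aggr <- rbinom(nrow(dd), 1L, cfg$aggression_rate) == 1L
  if (any(aggr)) {
    rows[[3L]] <- data.frame(day = dd$day[aggr], group = dd$group[aggr],
                             initiator = dd$male[aggr],
                             recipient = dd$infant[aggr],
                             behavior = "aggression",
                             stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  ev <- ev[order(ev$day), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Extract a model-ready table of generator truth
#'
#' Returns the generating dyad-day table with the requested direction's
#' binary response under the column name `response`, suitable for direct use
#' with [fit_binomial()] / [fit_ac_glmm()] in simulation studies that bypass
#' the observational assembly step.
#'
#' @param focal a [simulate_focal_data()] result.
#' @param direction `"infant"` (infant-initiated) or `"male"`.
#' @return the truth data frame with a `response` column.
#' @export
truth_model_table <- function(focal, direction = c("infant", "male")) {
  direction <- match.arg(direction)
  tt <- focal$truth
  tt$response <- if (direction == "infant") tt$response_infant else tt$response_male
  attr(tt, "direction") <- direction
  tt
}
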