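#' Simulate the study population
#'
#' Generates the roster and group-membership intervals: resident adult
#' females, immigrant adult males with gamma-distributed residence spells
#' (new males replace leavers so each group keeps its configured number of
#' concurrent male slots), and infants born to resident females. Each
#' conception is assigned a true sire by sampling among the males present in
#' the mother's group during the conceptive window, with probability
#' proportional to rank-standardized latent strength raised to
#' `paternity_skew`.
#'
#' Latent strength (one draw per adult) drives both agonistic outcomes in
#' [simulate_agonistic()] and the siring skew, so dominance measured from the
#' generated events correlates with reproductive success, as in the study
#' system being emulated.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_population`:
#'   \describe{
#'     \item{roster}{one row per individual: `id`, `sex`, `class`
#'       (`adult_female`/`adult_male`/`infant`), `group`, `birth_day`,
#'       `mother`, `sire`, `conc_start`, `conc_end`, `strength`,
#'       `tenure_days` (males: drawn residence length, uncensored).}
#'     \item{memberships}{`id`, `group`, `entry`, `exit` (inclusive study-day
#'       indices, clipped to the study horizon).}
#'     \item{config}{the generating configuration.}
#'   }
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  groups <- paste0("G", seq_len(cfg$n_groups))

  roster <- list()
  memb <- list()

  add_ind <- function(id, sex, class, group, birth_day = NA_integer_,
                      mother = NA_character_, sire = NA_character_,
                      conc_start = NA_integer_, conc_end = NA_integer_,
                      strength = NA_real_, tenure_days = NA_real_) {
    data.frame(id = id, sex = sex, class = class, group = group,
               birth_day = birth_day, mother = mother, sire = sire,
               conc_start = conc_start, conc_end = conc_end,
               strength = strength, tenure_days = tenure_days,
               stringsAsFactors = FALSE)
  }

  # resident adult females
  for (g in groups) {
    ids <- sprintf("%sF%02d", g, seq_len(cfg$females_per_group))
    roster[[length(roster) + 1L]] <- add_ind(
      ids, "F", "adult_female", g, strength = rnorm(length(ids)))
    memb[[length(memb) + 1L]] <- data.frame(
      id = ids, group = g, entry = 1L, exit = cfg$study_days,
      stringsAsFactors = FALSE)
  }

  # immigrant adult males: per slot, a chain of gamma-tenure residence spells
  shape <- (cfg$male_mean_tenure_days / cfg$male_tenure_sd_days)^2
  rate <- cfg$male_mean_tenure_days / cfg$male_tenure_sd_days^2
  for (g in groups) {
    m_idx <- 0L
    for (slot in seq_len(cfg$males_per_group)) {
      entry <- 1L
      while (entry <= cfg$study_days) {
        m_idx <- m_idx + 1L
        tenure <- max(1, round(rgamma(1L, shape = shape, rate = rate)))
        id <- sprintf("%sM%03d", g, m_idx)
        exit_raw <- entry + tenure - 1L
        roster[[length(roster) + 1L]] <- add_ind(
          id, "M", "adult_male", g, strength = rnorm(1L),
          tenure_days = tenure)
        memb[[length(memb) + 1L]] <- data.frame(
          id = id, group = g, entry = as.integer(entry),
          exit = as.integer(min(exit_raw, cfg$study_days)),
          stringsAsFactors = FALSE)
        # vacancy before the next immigrant fills the slot, so the number
        # of resident males fluctuates as in the emulated system
        entry <- exit_raw + 1L + rpois(1L, cfg$male_vacancy_mean_days)
      }
    }
  }

  roster <- do.call(rbind, roster)
  memberships <- do.call(rbind, memb)
  rownames(roster) <- rownames(memberships) <- NULL

  if (sum(roster$class == "adult_male") == 0L) {
    stop_data("impossible configuration: no adult males generated")
  }

  # births: per-female Bernoulli days, minimum spacing, conceptive window
  # fully inside the study horizon so candidate sires are defined
  males <- roster[roster$class == "adult_male", , drop = FALSE]
  min_birth <- cfg$gestation_days + cfg$conception_window_days
  infants <- list()
  i_idx <- setNames(rep(0L, length(groups)), groups)
  for (f in roster$id[roster$class == "adult_female"]) {
    g <- roster$group[roster$id == f]
    days <- seq.int(min_birth, cfg$study_days)
    hits <- days[runif(length(days)) < cfg$birth_rate]
    last <- -Inf
    for (b in hits) {
      if (b - last < cfg$birth_spacing_days) next
      conc_end <- b - cfg$gestation_days
      conc_start <- conc_end - cfg$conception_window_days + 1L
      cand <- memberships[memberships$group == g &
                            memberships$entry <= conc_end &
                            memberships$exit >= conc_start, , drop = FALSE]
      cand <- cand[cand$id %in% males$id, , drop = FALSE]
      if (nrow(cand) == 0L) next
      st <- males$strength[match(cand$id, males$id)]
      sire <- sample_sire(cand$id, st, cfg$paternity_skew)
      last <- b
      i_idx[g] <- i_idx[g] + 1L
      id <- sprintf("%sI%02d", g, i_idx[g])
      infants[[length(infants) + 1L]] <- data.frame(
        id = id, sex = sample(c("F", "M"), 1L), class = "infant", group = g,
        birth_day = as.integer(b), mother = f, sire = sire,
        conc_start = as.integer(conc_start), conc_end = as.integer(conc_end),
        strength = NA_real_, tenure_days = NA_real_,
        stringsAsFactors = FALSE)
      memberships <- rbind(memberships, data.frame(
        id = id, group = g, entry = as.integer(b), exit = cfg$study_days,
        stringsAsFactors = FALSE))
    }
  }
  if (length(infants) > 0L) {
    roster <- rbind(roster, do.call(rbind, infants))
  }
  rownames(roster) <- rownames(memberships) <- NULL

  structure(list(roster = roster, memberships = memberships, config = cfg),
            class = "sim_population")
}

# Sample one sire among eligible males with prob ~ (rank-standardized
# strength)^skew; skew 0 is uniform, skew Inf picks the strongest.
sample_sire <- function(ids, strength, skew) {
  if (length(ids) == 1L) return(ids)
  if (is.infinite(skew)) return(ids[which.max(strength)])
  w <- (rank(strength, ties.method = "first") / length(ids))^skew
  sample(ids, 1L, prob = w / sum(w))
}

#' @export
print.sim_population <- function(x, ...) {
  r <- x$roster
  cat("Synthetic study population\n")
  cat(sprintf("  groups: %d | adult females: %d | adult males: %d | infants: %d\n",
              x$config$n_groups, sum(r$class == "adult_female"),
              sum(r$class == "adult_male"), sum(r$class == "infant")))
  invisible(x)
}
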