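#' Share of interactions initiated by one party
#'
#' @param n_initiated events initiated by the party of interest.
#' @param n_total all events.
#' @return percentage (0-100).
#' @export
initiation_share <- function(n_initiated, n_total) {
  if (n_total <= 0) stop_data("n_total must be positive")
  100 * n_initiated / n_total
}

#' Ratio of scan counts (e.g. partner-absent vs partner-present)
#'
#' @param n_absent,n_present mean scan counts in the two conditions.
#' @return list with `ratio` (raw) and `rounded` (nearest integer, as such
#'   ratios are usually reported in prose).
#' @export
presence_ratio <- function(n_absent, n_present) {
  if (n_present <= 0) stop_data("n_present must be positive")
  r <- n_absent / n_present
  list(ratio = r, rounded = round(r))
}

#' Descriptive summary of male-infant interaction data
#'
#' Recomputes the pipeline's headline descriptive quantities from the raw
#' tables: total male-infant affiliative events and the share initiated by
#' infants; the affiliative share of all male-infant interactions; the mean
#' (per infant) scan counts near a male with the mother absent vs present
#' and their rounded ratio; the mirrored ratio near the mother with males
#' absent vs present; and the share of assigned sires still resident in the
#' infant's group at the end of its first year.
#'
#' Scan unions across males are approximated by summing dyad-day counts
#' (multi-male scans are rare at realistic proximity rates).
#'
#' @param interactions interaction events.
#' @param scans_daily infant-day scan counts.
#' @param prox_daily dyad-day proximity counts.
#' @param roster population roster.
#' @param memberships membership intervals.
#' @param paternity optional assignment table (`offspring`, `sire`);
#'   defaults to the roster's true sires.
#' @param behaviors affiliative behavior classes.
#' @return list of class `mi_descriptives`.
#' @export
descriptives <- function(interactions, scans_daily, prox_daily, roster,
                         memberships, paternity = NULL,
                         behaviors = c("approach", "groom", "friendly")) {
  cls <- setNames(roster$class, roster$id)
  mi <- interactions[(cls[interactions$initiator] == "infant" &
                        cls[interactions$recipient] == "adult_male") |
                       (cls[interactions$initiator] == "adult_male" &
                          cls[interactions$recipient] == "infant"), ]
  aff <- mi[mi$behavior %in% behaviors, ]
  n_aff <- nrow(aff)
  n_infant_init <- sum(cls[aff$initiator] == "infant")

  by_inf <- split(prox_daily, prox_daily$infant)
  near_male_mother_absent <- vapply(by_inf, function(d) {
    sum(d$male_scans - d$mm_scans)
  }, numeric(1L))
  near_male_mother_present <- vapply(by_inf, function(d) sum(d$mm_scans),
                                     numeric(1L))
  mother_tot <- tapply(scans_daily$mother_scans, scans_daily$infant, sum)
  mother_tot <- mother_tot[names(by_inf)]
  near_mother_male_absent <- mother_tot - near_male_mother_present

  r1 <- presence_ratio(mean(near_male_mother_absent),
                       mean(near_male_mother_present))
  r2 <- presence_ratio(mean(near_mother_male_absent),
                       mean(near_male_mother_present))

  # sire presence at the end of the infant's first year
  if (is.null(paternity)) {
    inf <- roster[roster$class == "infant", ]
    paternity <- data.frame(offspring = inf$id, sire = inf$sire,
                            stringsAsFactors = FALSE)
  }
  inf <- roster[match(paternity$offspring, roster$id), ]
  check_day <- pmin(inf$birth_day + 365L, max(memberships$exit))
  present <- is_resident(memberships, paternity$sire, check_day, inf$group)
  ok <- !is.na(paternity$sire)

  structure(list(
    n_male_infant_interactions = nrow(mi),
    n_affiliative = n_aff,
    affiliative_share_pct = initiation_share(n_aff, nrow(mi)),
    n_infant_initiated = n_infant_init,
    infant_initiated_share_pct = initiation_share(n_infant_init, n_aff),
    scans_near_male_mother_absent = mean(near_male_mother_absent),
    scans_near_male_mother_present = mean(near_male_mother_present),
    mother_absent_ratio = r1,
    scans_near_mother_male_absent = mean(near_mother_male_absent),
    male_absent_ratio = r2,
    father_present_at_one_year_pct =
      100 * mean(present[ok])), class = "mi_descriptives")
}

#' @export
print.mi_descriptives <- function(x, ...) {
  cat("Male-infant interaction descriptives\n")
  cat(sprintf("  male-infant interactions: %d (%.1f%% affiliative)\n",
              x$n_male_infant_interactions, x$affiliative_share_pct))
  cat(sprintf("  affiliations initiated by infants: %d of %d (%.1f%%)\n",
              x$n_infant_initiated, x$n_affiliative,
              x$infant_initiated_share_pct))
  cat(sprintf("  scans near a male: mother absent %.0f vs present %.0f (ratio ~%d)\n",
              x$scans_near_male_mother_absent,
              x$scans_near_male_mother_present, x$mother_absent_ratio$rounded))
  cat(sprintf("  scans near the mother: male absent %.0f vs present %.0f (ratio ~%d)\n",
              x$scans_near_mother_male_absent,
              x$scans_near_male_mother_present, x$male_absent_ratio$rounded))
  cat(sprintf("  sires present at offspring's first birthday: %.1f%%\n",
              x$father_present_at_one_year_pct))
  invisible(x)
}
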