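#' Binary dyad-day response from interaction events
#'
#' 1 iff at least one qualifying affiliative event occurred between the dyad
#' on the given day in the stated direction.
#'
#' @param events interaction events (`day`, `initiator`, `recipient`,
#'   `behavior`).
#' @param infant,male dyad member ids.
#' @param day study day.
#' @param direction `"infant"` (infant-initiated) or `"male"`.
#' @param behaviors affiliative behavior classes.
#' @return integer 0/1.
#' @export
daily_response <- function(events, infant, male, day,
                           direction = c("infant", "male"),
                           behaviors = c("approach", "groom", "friendly")) {
  direction <- match.arg(direction)
  ini <- if (direction == "infant") infant else male
  rec <- if (direction == "infant") male else infant
  as.integer(any(events$day == day & events$initiator == ini &
                   events$recipient == rec & events$behavior %in% behaviors))
}

#' Was a male present during an infant's conceptive window?
#'
#' @param memberships membership intervals.
#' @param male male id.
#' @param group the mother's group.
#' @param conc_start,conc_end conceptive window (inclusive day indices).
#' @return integer 0/1.
#' @export
conception_presence <- function(memberships, male, group, conc_start,
                                conc_end) {
  as.integer(any(memberships$id == male & memberships$group == group &
                   memberships$entry <= conc_end &
                   memberships$exit >= conc_start))
}

#' Assemble the daily dyad-level model table
#'
#' Builds one row per (focal infant, resident adult male, focal day) from
#' the observational tables: the binary affiliation response in the
#' requested direction, the standardized dominance ranks, the mother's
#' proximity scans, the running mother-male affiliation proportion, the
#' paternity and conception-presence indicators, the control covariates
#' (infant sex and age, number of resident males, seasonal sine/cosine,
#' male tenure) and the scan-count offset.
#'
#' Filters and transforms:
#' \itemize{
#'   \item rows exist only for focal days (`obs_scans >= 1`) and dyads
#'     co-resident in the infant's group that day;
#'   \item infant-days after the assigned sire left the group are omitted
#'     (whole focal follow dropped), as are infants without an assigned
#'     sire;
#'   \item mother presence is `log(x + 1)`-transformed, then all continuous
#'     predictors are z-scored study-wide (a constant column raises an
#'     error naming it); the seasonal sine/cosine are left on their natural
#'     scale;
#'   \item the mother-male affiliation proportion is cumulative from study
#'     start through the row's day (`window = "cumulative"`, default) or
#'     the same-day proportion (`window = "daily"`); days with no
#'     co-presence yet score 0;
#'   \item `present_at_conception` is included only for the male-initiated
#'     direction.
#' }
#'
#' @param direction `"infant"` or `"male"`.
#' @param roster,memberships population tables.
#' @param daily_ranks standardized daily ranks from [elo_standardize()].
#' @param scans_daily infant-day scan counts (`infant`, `day`, `group`,
#'   `obs_scans`, `mother_scans`).
#' @param prox_daily dyad-day proximity counts (`infant`, `male`, `day`,
#'   `male_scans`, `mm_scans`, `mm_affil`).
#' @param interactions interaction events.
#' @param paternity data frame `offspring`, `sire` (e.g. from
#'   [paternity_analysis()]); rows with `NA` sire are dropped with their
#'   infants.
#' @param conceptions data frame `infant`, `conc_start`, `conc_end`.
#' @param window aggregation window for the mother-male affiliation
#'   proportion.
#' @param behaviors affiliative behavior classes for the response.
#' @param origin_date calendar date of study day 1 (for the seasonal terms).
#' @return data frame of model rows with z-scored predictors (raw values
#'   kept under `*_raw`), a `response` column, `dyad` key and `obs_scans`
#'   offset. Transform means/SDs are stored in `attr(, "transforms")`.
#' @export
assemble_model_table <- function(direction = c("infant", "male"),
                                 roster, memberships, daily_ranks,
                                 scans_daily, prox_daily, interactions,
                                 paternity, conceptions,
                                 window = c("cumulative", "daily"),
                                 behaviors = c("approach", "groom",
                                               "friendly"),
                                 origin_date = "2008-10-01") {
  direction <- match.arg(direction)
  window <- match.arg(window)
  need_cols(scans_daily, c("infant", "day", "group", "obs_scans",
                           "mother_scans"), "scans_daily")
  need_cols(prox_daily, c("infant", "male", "day", "mm_scans", "mm_affil"),
            "prox_daily")
  need_cols(paternity, c("offspring", "sire"), "paternity")

  sires <- setNames(paternity$sire, paternity$offspring)
  sires <- sires[!is.na(sires)]
  sc <- scans_daily[scans_daily$infant %in% names(sires) &
                      scans_daily$obs_scans >= 1L, , drop = FALSE]

  # drop infant-days after the sire's emigration from the infant's group
  sire_res <- is_resident(memberships, sires[sc$infant], sc$day, sc$group)
  sc <- sc[sire_res, , drop = FALSE]
  if (nrow(sc) == 0L) stop_data("no focal rows remain after the sire filter")

  # expand infant-days over co-resident adult males
  males <- roster$id[roster$class == "adult_male"]
  mmemb <- memberships[memberships$id %in% males, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sc)), function(i) {
    d <- sc$day[i]
    spells <- mmemb[mmemb$group == sc$group[i] & mmemb$entry <= d &
                      mmemb$exit >= d, , drop = FALSE]
    if (nrow(spells) == 0L) return(NULL)
    data.frame(infant = sc$infant[i], male = spells$id, day = d,
               group = sc$group[i], obs_scans = sc$obs_scans[i],
               mother_scans = sc$mother_scans[i],
               male_tenure_raw = d - spells$entry,
               n_males_raw = nrow(spells),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  tab <- tab[order(tab$infant, tab$male, tab$day), , drop = FALSE]
  rownames(tab) <- NULL

  # response: any qualifying event of the dyad-day in the right direction
  aff <- interactions[interactions$behavior %in% behaviors, , drop = FALSE]
  if (direction == "infant") {
    ev_key <- paste(aff$initiator, aff$recipient, aff$day)
    tab$response <- as.integer(paste(tab$infant, tab$male, tab$day) %in% ev_key)
  } else {
    ev_key <- paste(aff$initiator, aff$recipient, aff$day)
    tab$response <- as.integer(paste(tab$male, tab$infant, tab$day) %in% ev_key)
  }

  # ranks
  tab$mother <- roster$mother[match(tab$infant, roster$id)]
  rk <- paste(daily_ranks$id, daily_ranks$day)
  tab$male_rank_raw <- daily_ranks$rank_std[match(paste(tab$male, tab$day), rk)]
  tab$mother_rank_raw <- daily_ranks$rank_std[match(paste(tab$mother, tab$day), rk)]
  if (anyNA(tab$male_rank_raw) || anyNA(tab$mother_rank_raw)) {
    stop_data("daily ranks do not cover all resident adults on all focal days")
  }

  # mother-male affiliation proportion
  px <- prox_daily[order(prox_daily$infant, prox_daily$male, prox_daily$day), ]
  pk <- paste(px$infant, px$male)
  if (window == "cumulative") {
    num <- ave(px$mm_affil, pk, FUN = cumsum)
    den <- ave(px$mm_scans, pk, FUN = cumsum)
  } else {
    num <- px$mm_affil
    den <- px$mm_scans
  }
  bond <- ifelse(den > 0, num / den, 0)
  mt <- match(paste(tab$infant, tab$male, tab$day),
              paste(px$infant, px$male, px$day))
  tab$bond_raw <- ifelse(is.na(mt), 0, bond[mt])

  # paternity and conception presence
  tab$paternity <- as.integer(sires[tab$infant] == tab$male)
  if (direction == "male") {
    need_cols(conceptions, c("infant", "conc_start", "conc_end"),
              "conceptions")
    ci <- match(tab$infant, conceptions$infant)
    ukey <- paste(tab$male, tab$group, conceptions$conc_start[ci],
                  conceptions$conc_end[ci])
    uu <- !duplicated(ukey)
    pres <- setNames(mapply(conception_presence,
                            male = tab$male[uu], group = tab$group[uu],
                            conc_start = conceptions$conc_start[ci][uu],
                            conc_end = conceptions$conc_end[ci][uu],
                            MoreArgs = list(memberships = memberships)),
                     ukey[uu])
    tab$present_at_conception <- as.integer(pres[ukey])
  }

  # controls
  tab$infant_sex <- roster$sex[match(tab$infant, roster$id)]
  tab$infant_age_raw <- tab$day - roster$birth_day[match(tab$infant, roster$id)]
  doy <- day_of_year(tab$day, origin_date)
  tab$season_sin <- sin(2 * pi * doy / 365.25)
  tab$season_cos <- cos(2 * pi * doy / 365.25)
  tab$dyad <- paste(tab$infant, tab$male)

  # transforms
  zs <- list()
  zcol <- function(raw, name) {
    m <- mean(raw); s <- sd(raw)
    zs[[name]] <<- c(mean = m, sd = s)
    z_transform(raw, name)
  }
  tab$male_rank <- zcol(tab$male_rank_raw, "male_rank")
  tab$mother_rank <- zcol(tab$mother_rank_raw, "mother_rank")
  tab$mother_presence <- zcol(log1p(tab$mother_scans), "mother_presence")
  tab$mother_male_affiliation <- zcol(tab$bond_raw, "mother_male_affiliation")
  tab$infant_age <- zcol(tab$infant_age_raw, "infant_age")
  tab$n_males <- zcol(tab$n_males_raw, "n_males")
  tab$male_tenure <- zcol(tab$male_tenure_raw, "male_tenure")

  attr(tab, "direction") <- direction
  attr(tab, "transforms") <- zs
  attr(tab, "window") <- window
  tab
}
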