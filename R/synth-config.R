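#' Configuration for the synthetic study generator
#'
#' Bundles every tunable of the synthetic-data module. Defaults emulate the
#' field conditions the pipeline was designed for: three wild groups of
#' crested macaques followed for two years, each with a stable core of adult
#' females and a turnover pool of immigrant adult males (gamma-distributed
#' tenures, mean 766.5 and SD 396.7 days), strong rank skew in siring
#' probability, 12 microsatellite loci of ~6 alleles typed from low-quality
#' fecal DNA (allelic dropout, replicate PCRs), and daily dyadic affiliation
#' propensities driven by a configurable log-odds linear predictor plus a
#' per-dyad AR(1) latent process on the logit scale.
#'
#' @param n_groups number of social groups.
#' @param females_per_group adult females per group (resident throughout).
#' @param males_per_group concurrent adult-male slots per group.
#' @param study_days length of the study horizon in days.
#' @param male_mean_tenure_days,male_tenure_sd_days gamma tenure distribution
#'   for male residence spells, in days.
#' @param male_vacancy_mean_days Poisson mean of the vacancy (days) between
#'   a male's departure and the next immigrant filling the slot.
#' @param birth_rate per female-day probability of a birth (subject to a
#'   minimum spacing of `birth_spacing_days` between births).
#' @param birth_spacing_days minimum days between two births of one female.
#' @param gestation_days days from conception to birth used to locate the
#'   conceptive cycle.
#' @param conception_window_days length of the conceptive window; the window
#'   is the `conception_window_days` consecutive days ending
#'   `gestation_days` before birth.
#' @param msat_loci,alleles_per_locus microsatellite panel dimensions.
#' @param dropout_rate per-allele allelic dropout probability per PCR
#'   replicate (heterozygotes only).
#' @param misprint_rate per shown allele probability of substitution by a
#'   random allele (false allele / misprint).
#' @param pcr_replicates independent PCR replicates per individual x locus.
#' @param paternity_skew exponent applied to rank-standardized male strength
#'   when sampling the sire among males present in the conceptive window;
#'   0 gives uniform sampling, `Inf` a deterministic top-male sire.
#' @param true_effects named numeric vector of log-odds effects applied to
#'   the (z-scored) daily dyad predictors when generating affiliation.
#'   Recognised components: `male_rank`, `mother_rank`, `mother_presence`,
#'   `mother_male_affiliation`, `paternity`, `present_at_conception`
#'   (the last acts on the male-initiated direction only); interaction
#'   terms such as `"male_rank:mother_male_affiliation"` contribute the
#'   product of their components.
#' @param intercept_infant,intercept_male baseline log-odds of a dyad-day
#'   affiliation initiated by the infant / by the male.
#' @param ar1_rho,ar1_sd lag-1 correlation and stationary SD of the per-dyad
#'   AR(1) latent term added to both directions' linear predictors.
#' @param focal_age_days infants are followed from birth for this many days.
#' @param scans_per_follow 1-min scans per 30-min focal follow.
#' @param follows_per_day_mean Poisson mean of focal follows per infant-day
#'   (truncated to at least one).
#' @param p_mother_near,p_male_near per-scan probability that the mother /
#'   a given resident male is within 2.5 m of the focal infant (per male, so
#'   the chance of being near any male scales with the number of residents).
#' @param bond_shape1,bond_shape2 beta parameters of the latent mother-male
#'   affiliation propensity per dyad (probability of an affiliation flag on a
#'   co-presence scan).
#' @param agonistic_per_group_day Poisson mean of decided agonistic events
#'   per group-day.
#' @param contest_scale logistic scale of the strength difference in
#'   P(stronger wins).
#' @param extra_events_mean Poisson mean of additional affiliative events on
#'   a dyad-day whose binary response is 1 (at least one is always emitted).
#' @param aggression_rate per dyad-day probability of a male-to-infant
#'   aggressive event (kept for descriptive ratios only).
#' @param origin_date calendar date of study day 1 (ISO string).
#' @param seed integer master seed; each generator stage derives its own
#'   stream from it, so a config reproduces byte-identical data.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 3L,
                       females_per_group = 18L,
                       males_per_group = 7L,
                       study_days = 730L,
                       male_mean_tenure_days = 766.5,
                       male_tenure_sd_days = 396.7,
                       male_vacancy_mean_days = 45,
                       birth_rate = 1.1e-3,
                       birth_spacing_days = 365L,
                       gestation_days = 165L,
                       conception_window_days = 14L,
                       msat_loci = 12L,
                       alleles_per_locus = 6L,
                       dropout_rate = 0.05,
                       misprint_rate = 0.01,
                       pcr_replicates = 6L,
                       paternity_skew = 4,
                       true_effects = c(male_rank = 0.15,
                                        mother_presence = -0.2,
                                        mother_male_affiliation = 0.1),
                       intercept_infant = qlogis(0.043),
                       intercept_male = qlogis(0.019),
                       ar1_rho = 0.5,
                       ar1_sd = 0.5,
                       focal_age_days = 365L,
                       scans_per_follow = 30L,
                       follows_per_day_mean = 2,
                       p_mother_near = 0.17,
                       p_male_near = 0.022,
                       bond_shape1 = 2,
                       bond_shape2 = 8,
                       agonistic_per_group_day = 2,
                       contest_scale = 0.35,
                       extra_events_mean = 0.5,
                       aggression_rate = 0.004,
                       origin_date = "2008-10-01",
                       seed = 1L) {
  cfg <- list(
    n_groups = as.integer(n_groups),
    females_per_group = as.integer(females_per_group),
    males_per_group = as.integer(males_per_group),
    study_days = as.integer(study_days),
    male_mean_tenure_days = male_mean_tenure_days,
    male_tenure_sd_days = male_tenure_sd_days,
    male_vacancy_mean_days = male_vacancy_mean_days,
    birth_rate = birth_rate,
    birth_spacing_days = as.integer(birth_spacing_days),
    gestation_days = as.integer(gestation_days),
    conception_window_days = as.integer(conception_window_days),
    msat_loci = as.integer(msat_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    dropout_rate = dropout_rate,
    misprint_rate = misprint_rate,
    pcr_replicates = as.integer(pcr_replicates),
    paternity_skew = paternity_skew,
    true_effects = true_effects,
    intercept_infant = intercept_infant,
    intercept_male = intercept_male,
    ar1_rho = ar1_rho,
    ar1_sd = ar1_sd,
    focal_age_days = as.integer(focal_age_days),
    scans_per_follow = as.integer(scans_per_follow),
    follows_per_day_mean = follows_per_day_mean,
    p_mother_near = p_mother_near,
    p_male_near = p_male_near,
    bond_shape1 = bond_shape1,
    bond_shape2 = bond_shape2,
    agonistic_per_group_day = agonistic_per_group_day,
    contest_scale = contest_scale,
    extra_events_mean = extra_events_mean,
    aggression_rate = aggression_rate,
    origin_date = origin_date,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  counts <- c("n_groups", "females_per_group", "males_per_group",
              "study_days", "msat_loci", "alleles_per_locus",
              "pcr_replicates", "focal_age_days", "scans_per_follow",
              "conception_window_days", "gestation_days")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1L) {
      stop_data("invalid configuration: '%s' must be a count >= 1", nm)
    }
  }
  probs <- c("birth_rate", "dropout_rate", "misprint_rate",
             "p_mother_near", "p_male_near", "aggression_rate")
  for (nm in probs) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) {
      stop_data("invalid configuration: '%s' must be a probability in [0,1]",
                nm)
    }
  }
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) {
    stop_data("invalid configuration: 'ar1_rho' must lie in [0,1)")
  }
  if (cfg$ar1_sd < 0) stop_data("invalid configuration: 'ar1_sd' must be >= 0")
  if (cfg$male_mean_tenure_days <= 0) {
    stop_data("invalid configuration: 'male_mean_tenure_days' must be > 0")
  }
  if (cfg$paternity_skew < 0) {
    stop_data("invalid configuration: 'paternity_skew' must be >= 0")
  }
  known <- c("male_rank", "mother_rank", "mother_presence",
             "mother_male_affiliation", "paternity", "present_at_conception")
  comps <- unique(unlist(strsplit(names(cfg$true_effects), ":", fixed = TRUE)))
  bad <- setdiff(comps, known)
  if (length(bad) > 0L) {
    stop_data("unknown true_effects component(s): %s (known: %s)",
              paste(bad, collapse = ", "), paste(known, collapse = ", "))
  }
  cfg
}
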