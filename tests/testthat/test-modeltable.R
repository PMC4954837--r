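# Handcrafted observational tables: one infant (i1, born day 10, mother f1,
# sire mA), two resident males (mB emigrates after day 12), focal follows on
# days 10-14 and 16 (no follow on day 15).
mt_fixture <- function(sire_exit = 210L) {
  roster <- data.frame(
    id = c("f1", "mA", "mB", "i1"),
    sex = c("F", "M", "M", "F"),
    class = c("adult_female", "adult_male", "adult_male", "infant"),
    group = "G1",
    birth_day = c(NA, NA, NA, 10L),
    mother = c(NA, NA, NA, "f1"),
    sire = c(NA, NA, NA, "mA"),
    stringsAsFactors = FALSE)
  memb <- data.frame(id = c("f1", "mA", "mB", "i1"), group = "G1",
                     entry = 1L, exit = c(210L, sire_exit, 12L, 210L))
  days <- c(10:14, 16L)
  scans <- data.frame(infant = "i1", day = days, group = "G1",
                      obs_scans = c(60L, 30L, 60L, 90L, 60L, 30L),
                      mother_scans = c(10L, 5L, 9L, 12L, 7L, 3L))
  ranks <- rbind(
    data.frame(id = "mA", day = 1:20, rank_std = 1),
    data.frame(id = "mB", day = 1:20, rank_std = 0),
    data.frame(id = "f1", day = 1:20,
               rank_std = rep(c(0.3, 0.6), length.out = 20L)))
  prox <- data.frame(infant = "i1",
                     male = c("mA", "mA", "mA", "mB"),
                     day = c(10L, 11L, 12L, 10L),
                     male_scans = c(4L, 3L, 2L, 5L),
                     mm_scans = c(2L, 2L, 0L, 1L),
                     mm_affil = c(1L, 0L, 0L, 1L))
  inter <- data.frame(
    day = c(11L, 11L, 12L, 13L),
    group = "G1",
    initiator = c("i1", "i1", "mA", "mA"),
    recipient = c("mA", "mA", "i1", "i1"),
    behavior = c("approach", "groom", "approach", "aggression"),
    stringsAsFactors = FALSE)
  pat <- data.frame(offspring = "i1", sire = "mA", stringsAsFactors = FALSE)
  conc <- data.frame(infant = "i1", conc_start = 2L, conc_end = 8L)
  list(roster = roster, memb = memb, scans = scans, ranks = ranks,
       prox = prox, inter = inter, pat = pat, conc = conc)
}

test_that("dyad-day rows, responses and filters follow the assembly rules", {
  fx <- mt_fixture()
  tab <- assemble_model_table("infant", fx$roster, fx$memb, fx$ranks,
                              fx$scans, fx$prox, fx$inter, fx$pat, fx$conc)
  # mB present only through day 12: 3 dyad-days with mB, 6 with mA
  expect_identical(nrow(tab), 9L)
  expect_identical(sum(tab$male == "mB"), 3L)
  # the affiliative response marks only the infant-initiated dyad-day
  expect_identical(tab$response[tab$male == "mA" & tab$day == 11L], 1L)
  expect_identical(sum(tab$response), 1L)
  # aggression-only day 13 stays 0
  expect_identical(tab$response[tab$male == "mA" & tab$day == 13L], 0L)

  tabm <- assemble_model_table("male", fx$roster, fx$memb, fx$ranks,
                               fx$scans, fx$prox, fx$inter, fx$pat, fx$conc)
  expect_identical(tabm$response[tabm$male == "mA" & tabm$day == 12L], 1L)
  expect_identical(sum(tabm$response), 1L)
  # conception presence only in the male-direction table
  expect_true("present_at_conception" %in% names(tabm))
  expect_false("present_at_conception" %in% names(tab))
  expect_true(all(tabm$present_at_conception[tabm$male == "mA"] == 1L))
  expect_true(all(tabm$present_at_conception[tabm$male == "mB"] == 1L))
})

test_that("the mother-male affiliation proportion accumulates through time", {
  fx <- mt_fixture()
  tab <- assemble_model_table("infant", fx$roster, fx$memb, fx$ranks,
                              fx$scans, fx$prox, fx$inter, fx$pat, fx$conc)
  a <- tab[tab$male == "mA", ]
  # day 10: 1/2; day 11: 1/4 cumulative; day 12: unchanged (no co-presence);
  # later days carry no proximity rows and keep 0 by the missing-row rule
  expect_equal(a$bond_raw[a$day == 10L], 0.5)
  expect_equal(a$bond_raw[a$day == 11L], 0.25)
  expect_equal(a$bond_raw[a$day == 12L], 0.25)
  tabd <- assemble_model_table("infant", fx$roster, fx$memb, fx$ranks,
                               fx$scans, fx$prox, fx$inter, fx$pat, fx$conc,
                               window = "daily")
  ad <- tabd[tabd$male == "mA", ]
  expect_equal(ad$bond_raw[ad$day == 11L], 0)
})

test_that("z-scored predictors have mean 0 and sd 1; constants are refused", {
  fx <- mt_fixture()
  tab <- assemble_model_table("infant", fx$roster, fx$memb, fx$ranks,
                              fx$scans, fx$prox, fx$inter, fx$pat, fx$conc)
  for (cc in c("male_rank", "mother_rank", "mother_presence",
               "mother_male_affiliation", "infant_age", "n_males",
               "male_tenure")) {
    expect_equal(mean(tab[[cc]]), 0, tolerance = 1e-9)
    expect_equal(sd(tab[[cc]]), 1, tolerance = 1e-9)
  }
  # seasonal terms follow the day-of-year harmonics
  doy <- as.integer(format(day_to_date(tab$day), "%j"))
  expect_equal(tab$season_sin, sin(2 * pi * doy / 365.25))
  expect_equal(tab$season_cos, cos(2 * pi * doy / 365.25))

  fx$ranks$rank_std[fx$ranks$id == "f1"] <- 0.5  # constant mother rank
  expect_error(
    assemble_model_table("infant", fx$roster, fx$memb, fx$ranks, fx$scans,
                         fx$prox, fx$inter, fx$pat, fx$conc),
    "mother_rank")
})

test_that("focal days after the sire's emigration are dropped entirely", {
  fx <- mt_fixture(sire_exit = 12L)
  fx$memb$exit[fx$memb$id == "mB"] <- 11L  # keep the male count varying
  tab <- assemble_model_table("infant", fx$roster, fx$memb, fx$ranks,
                              fx$scans, fx$prox, fx$inter, fx$pat, fx$conc)
  expect_lte(max(tab$day), 12L)
  # both dyads disappear from day 13 on, not just the sire's rows
  expect_identical(sort(unique(tab$day)), c(10L, 11L, 12L))
})

test_that("row counts match a brute-force recount on generated data", {
  cfg <- tiny_config(seed = 14L)
  pop <- simulate_population(cfg)
  foc <- simulate_focal_data(pop, cfg)
  ag <- simulate_agonistic(pop, cfg)
  daily <- elo_standardize(elo_daily(elo_update(ag, pop$memberships),
                                     pop$roster, pop$memberships,
                                     days = seq_len(cfg$study_days)))
  inf <- pop$roster[pop$roster$class == "infant", ]
  pat <- data.frame(offspring = inf$id, sire = inf$sire,
                    stringsAsFactors = FALSE)
  conc <- data.frame(infant = inf$id, conc_start = inf$conc_start,
                     conc_end = inf$conc_end, stringsAsFactors = FALSE)
  tab <- assemble_model_table("infant", pop$roster, pop$memberships, daily,
                              foc$scans_daily, foc$prox_daily,
                              foc$interactions, pat, conc)
  m <- pop$memberships
  males <- pop$roster$id[pop$roster$class == "adult_male"]
  expected <- 0L
  for (i in seq_len(nrow(foc$scans_daily))) {
    s <- foc$scans_daily[i, ]
    sire <- inf$sire[match(s$infant, inf$id)]
    sire_here <- any(m$id == sire & m$group == s$group &
                       m$entry <= s$day & m$exit >= s$day)
    if (!sire_here) next
    n_m <- sum(m$id %in% males & m$group == s$group &
                 m$entry <= s$day & m$exit >= s$day)
    expected <- expected + n_m
  }
  expect_identical(nrow(tab), expected)
  # the assigned sire is always conception-present under generator truth
  for (i in seq_len(nrow(inf))) {
    expect_identical(
      conception_presence(m, inf$sire[i], inf$group[i], inf$conc_start[i],
                          inf$conc_end[i]), 1L)
  }
})
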