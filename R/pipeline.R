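#' Write a synthetic dataset to CSV files
#'
#' Emits the standard file set consumed by the analysis stages:
#' `roster.csv`, `memberships.csv`, `agonistic.csv`, `scans.csv` (infant-day
#' grain), `proximity.csv` (dyad-day grain), `interactions.csv`,
#' `pcr_replicates.csv`, `conceptions.csv`. Day indices are written as
#' ISO-8601 dates against the configuration's origin.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_synth_csvs <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  org <- dataset$config$origin_date
  pop <- dataset$population
  w <- function(df, file, day_cols = "day") {
    for (dc in intersect(day_cols, names(df))) {
      df[[dc]] <- as.character(day_to_date(df[[dc]], org))
    }
    path <- file.path(dir, file)
    write.csv(df, path, row.names = FALSE)
    path
  }
  roster <- pop$roster
  roster$birth_date <- ifelse(is.na(roster$birth_day), NA,
                              as.character(day_to_date(roster$birth_day, org)))
  inf <- roster[roster$class == "infant", ]
  conceptions <- data.frame(infant = inf$id, mother = inf$mother,
                            group = inf$group, conc_start = inf$conc_start,
                            conc_end = inf$conc_end, stringsAsFactors = FALSE)
  paths <- c(
    w(roster[, c("id", "sex", "class", "group", "birth_date", "mother",
                 "sire")], "roster.csv"),
    w(pop$memberships, "memberships.csv", c("entry", "exit")),
    w(dataset$agonistic, "agonistic.csv"),
    w(dataset$focal$scans_daily, "scans.csv"),
    w(dataset$focal$prox_daily, "proximity.csv"),
    w(dataset$focal$interactions, "interactions.csv"),
    w(dataset$genotypes$replicates, "pcr_replicates.csv"),
    w(conceptions, "conceptions.csv", c("conc_start", "conc_end")))
  invisible(paths)
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Orchestrates every stage in dependency order: data generation, Elo
#' ratings with daily standardization, consensus genotyping with locus
#' statistics, paternity assignment, dyadic permutation tests, model-table
#' assembly, optionally the AC-GLMM fits, and the descriptive summary. All
#' tabular outputs are written under `out_dir` together with a
#' reproducibility manifest (`manifest.json`: seed, parameters, file
#' hashes), which is identical across reruns with the same configuration.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param n_perm permutations for the dyadic preference tests.
#' @param fit one of `"none"`, `"glm"` (no random terms; fast smoke fits)
#'   or `"glmm"` (random intercepts).
#' @param min_maternity_loci maternity-check locus threshold; lower it for
#'   deliberately tiny marker panels.
#' @return list with every stage's in-memory result plus `manifest`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = tempfile("macaffil_"),
                         n_perm = 1000L, fit = c("none", "glm", "glmm"),
                         min_maternity_loci = 8L) {
  fit <- match.arg(fit)
  dataset <- simulate_dataset(cfg)
  pop <- dataset$population
  write_synth_csvs(dataset, out_dir)

  # dominance
  tl <- elo_update(dataset$agonistic, pop$memberships)
  daily <- elo_standardize(
    elo_daily(tl, pop$roster, pop$memberships,
              days = seq_len(cfg$study_days)))
  write.csv(daily, file.path(out_dir, "daily_ranks.csv"), row.names = FALSE)

  # genotypes
  genos <- suppressWarnings(
    call_consensus_all(dataset$genotypes$replicates,
                       on_contamination = "unresolved"))
  write.csv(genos, file.path(out_dir, "genotypes.csv"), row.names = FALSE)
  freqs <- allele_frequencies(genos)
  lstats <- locus_summary(genos)
  write.csv(lstats, file.path(out_dir, "locus_stats.csv"), row.names = FALSE)

  # paternity
  inf <- pop$roster[pop$roster$class == "infant", ]
  offspring_tab <- data.frame(offspring = inf$id, mother = inf$mother,
                              group = inf$group, conc_start = inf$conc_start,
                              conc_end = inf$conc_end,
                              stringsAsFactors = FALSE)
  males <- pop$roster$id[pop$roster$class == "adult_male"]
  paternity <- paternity_analysis(genos, offspring_tab, males,
                                  pop$memberships, freqs,
                                  min_maternity_loci = min_maternity_loci)
  write.csv(paternity, file.path(out_dir, "paternity.csv"),
            row.names = FALSE)

  # dyadic preference permutation tests
  perm <- list()
  for (g in unique(pop$roster$group)) {
    for (dir_ in c("infant_to_male", "male_to_infant")) {
      dt <- tryCatch(
        build_dyad_table(dataset$focal$interactions, pop$roster,
                         pop$memberships, g, dir_,
                         period = c(1L, cfg$study_days)),
        error = function(e) NULL)
      if (is.null(dt)) next
      ev <- dyad_table_events(dataset$focal$interactions, pop$roster,
                              pop$memberships, g, dir_,
                              period = c(1L, cfg$study_days))
      pt <- tryCatch(permutation_test(ev, n_perm = n_perm,
                                      seed = cfg$seed + 10L),
                     error = function(e) NULL)
      if (is.null(pt)) next
      perm[[paste(g, dir_, sep = "_")]] <- pt
    }
  }
  perm_df <- do.call(rbind, lapply(names(perm), function(k) {
    data.frame(key = k, n = sum(perm[[k]]$tab), chi2 = perm[[k]]$statistic,
               p = perm[[k]]$p_value, stringsAsFactors = FALSE)
  }))
  if (!is.null(perm_df)) {
    write.csv(perm_df, file.path(out_dir, "permtest.csv"), row.names = FALSE)
  }

  # model tables
  conceptions <- offspring_tab[, c("offspring", "conc_start", "conc_end")]
  names(conceptions)[1L] <- "infant"
  tables <- list()
  for (d in c("infant", "male")) {
    tables[[d]] <- assemble_model_table(
      d, pop$roster, pop$memberships, daily, dataset$focal$scans_daily,
      dataset$focal$prox_daily, dataset$focal$interactions,
      paternity[, c("offspring", "sire")], conceptions,
      origin_date = cfg$origin_date)
    write.csv(tables[[d]], file.path(out_dir,
                                     sprintf("model_table_%s.csv", d)),
              row.names = FALSE)
  }

  fits <- NULL
  if (fit != "none") {
    fits <- list()
    for (d in c("infant", "male")) {
      sp <- model_spec(d,
                       random_intercepts = if (fit == "glmm") {
                         c("male", "infant", "dyad", "group", "day")
                       } else character(0L))
      fits[[d]] <- fit_ac_glmm(tables[[d]], sp)
    }
  }

  desc <- descriptives(dataset$focal$interactions,
                       dataset$focal$scans_daily, dataset$focal$prox_daily,
                       pop$roster, pop$memberships,
                       paternity[, c("offspring", "sire")])

  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "true_effects")],
    true_effects = as.list(cfg$true_effects),
    files = as.list(tools::md5sum(sort(list.files(out_dir,
                                                  pattern = "\\.csv$",
                                                  full.names = TRUE)))))
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  list(dataset = dataset, daily_ranks = daily, genotypes = genos,
       locus_stats = lstats, freqs = freqs, paternity = paternity,
       permtests = perm, model_tables = tables, fits = fits,
       descriptives = desc, manifest = manifest, out_dir = out_dir)
}

# Events underlying a dyad table (same filters), for the permutation test.
dyad_table_events <- function(events, roster, memberships, group, direction,
                              period,
                              behaviors = c("approach", "groom",
                                            "friendly")) {
  cls <- setNames(roster$class, roster$id)
  ev <- events[events$group == group & events$behavior %in% behaviors, ]
  init_cls <- if (direction == "infant_to_male") "infant" else "adult_male"
  ev <- ev[cls[ev$initiator] %in% init_cls, , drop = FALSE]
  full <- memberships$id[memberships$group == group &
                           memberships$entry <= period[1L] &
                           memberships$exit >= period[2L]]
  male_col <- if (direction == "infant_to_male") "recipient" else "initiator"
  ev[ev[[male_col]] %in% full, , drop = FALSE]
}

#' Read a synthetic dataset back from its CSV files
#'
#' Counterpart of [write_synth_csvs()]: loads the file set from `dir` and
#' converts ISO dates back to integer study-day indices.
#'
#' @param dir directory holding the CSV files.
#' @param origin_date calendar date of study day 1.
#' @return list with `roster`, `memberships`, `agonistic`, `scans_daily`,
#'   `prox_daily`, `interactions`, `replicates`, `conceptions`.
#' @export
read_synth_csvs <- function(dir, origin_date = "2008-10-01") {
  rd <- function(file, day_cols = "day") {
    df <- read.csv(file.path(dir, file), stringsAsFactors = FALSE,
                   colClasses = "character")
    for (nm in names(df)) {
      if (nm %in% day_cols) {
        df[[nm]] <- date_to_day(df[[nm]], origin_date)
      } else if (all(grepl("^-?[0-9.]+$", df[[nm]][!is.na(df[[nm]])]))) {
        num <- suppressWarnings(as.numeric(df[[nm]]))
        if (!anyNA(num[!is.na(df[[nm]])])) {
          df[[nm]] <- if (all(num == round(num), na.rm = TRUE)) {
            as.integer(num)
          } else num
        }
      }
    }
    df
  }
  roster <- rd("roster.csv", day_cols = "birth_date")
  names(roster)[names(roster) == "birth_date"] <- "birth_day"
  list(roster = roster,
       memberships = rd("memberships.csv", c("entry", "exit")),
       agonistic = rd("agonistic.csv"),
       scans_daily = rd("scans.csv"),
       prox_daily = rd("proximity.csv"),
       interactions = rd("interactions.csv"),
       replicates = rd("pcr_replicates.csv"),
       conceptions = rd("conceptions.csv", c("conc_start", "conc_end")))
}
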