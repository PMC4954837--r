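#' Gaussian-kernel temporal autocorrelation term
#'
#' For each row i, the weighted average of the residuals of all *other* rows
#' sharing the same key (same infant, or same male), with Gaussian weights
#' in the time lag: `w_ij = exp(-dt_ij^2 / (2 sigma^2))`,
#' `AC_i = sum_j w_ij r_j / sum_j w_ij` over `j != i` with `key_j = key_i`.
#' Rows with no same-key partner get 0.
#'
#' Computed exactly via per-day binning (rows on the same day share
#' weights), so cost is O(rows x unique days) per key rather than
#' O(rows^2).
#'
#' @param day integer vector of row days.
#' @param key grouping key per row (e.g. infant id or male id).
#' @param resid residuals per row (response scale: `y - fitted p`).
#' @param sigma Gaussian kernel SD in days (> 0).
#' @return numeric vector of AC values, one per row.
#' @export
ac_term <- function(day, key, resid, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop_data("sigma must be a single positive number")
  }
  n <- length(day)
  stopifnot(length(key) == n, length(resid) == n)
  out <- numeric(n)
  for (ix in split(seq_len(n), key)) {
    if (length(ix) < 2L) next
    d <- day[ix]; r <- resid[ix]
    ud <- sort(unique(d))
    bi <- match(d, ud)
    s_d <- vapply(split(r, bi), sum, numeric(1L))
    n_d <- tabulate(bi, nbins = length(ud))
    w <- exp(-outer(d, ud, "-")^2 / (2 * sigma^2))
    # the own day-bin has weight exactly 1: zero it in the kernel matrix and
    # add the bin's other-row contribution separately, which excludes the
    # own residual without cancellation when all partners are remote
    w[cbind(seq_along(d), bi)] <- 0
    num <- as.vector(w %*% s_d) + (s_d[bi] - r)
    den <- as.vector(w %*% n_d) + (n_d[bi] - 1)
    out[ix] <- ifelse(den > 0, num / den, 0)
  }
  out
}

#' Model specification for the dyad-day binomial GLMMs
#'
#' Defines the fixed test predictors (main effects, the five two-way and
#' two three-way interactions among male rank, paternity, mother presence
#' and mother-male affiliation; the male-initiated direction adds presence
#' at conception), the control terms, the AC-term keys, the offset and the
#' random-effect structure. The null specification keeps the AC terms,
#' offset, controls and random effects but drops every test predictor.
#'
#' @param direction `"infant"` or `"male"`.
#' @param include_interactions include the interaction structure (default
#'   TRUE).
#' @param random_intercepts grouping factors for random intercepts.
#' @param random_slopes character vector of `"term | group"` uncorrelated
#'   random-slope declarations (e.g. `"male_rank | infant"`); default none,
#'   a reduced structure for desk-scale fits. `slope_preset = "reduced"`
#'   adds rank and mother-presence slopes within infant and male;
#'   `"full"` adds every test main effect and interaction within infant,
#'   male and dyad.
#' @param slope_preset optional shortcut overriding `random_slopes`.
#' @param controls control covariates (estimated but not interpreted).
#' @param response,offset_col column names of the response and the offset
#'   scan count.
#' @return list of class `acglmm_spec`.
#' @export
model_spec <- function(direction = c("infant", "male"),
                       include_interactions = TRUE,
                       random_intercepts = c("male", "infant", "dyad",
                                             "group", "day"),
                       random_slopes = character(0L),
                       slope_preset = NULL,
                       controls = c("infant_sex", "infant_age", "n_males",
                                    "season_sin", "season_cos",
                                    "male_tenure"),
                       response = "response", offset_col = "obs_scans") {
  direction <- match.arg(direction)
  mains <- c("male_rank", "mother_rank", "mother_presence",
             "mother_male_affiliation", "paternity")
  if (direction == "male") mains <- c(mains, "present_at_conception")
  two_way <- c("male_rank:paternity", "male_rank:mother_presence",
               "paternity:mother_presence",
               "male_rank:mother_male_affiliation",
               "paternity:mother_male_affiliation")
  three_way <- c("male_rank:paternity:mother_presence",
                 "male_rank:paternity:mother_male_affiliation")
  test_terms <- if (include_interactions) c(mains, two_way, three_way) else mains
  if (!is.null(slope_preset)) {
    slope_terms <- switch(slope_preset,
      none = character(0L),
      reduced = c("male_rank | infant", "mother_presence | infant",
                  "male_rank | male", "mother_presence | male"),
      full = as.vector(outer(test_terms, c("infant", "male", "dyad"),
                             paste, sep = " | ")),
      stop_data("unknown slope_preset '%s'", slope_preset))
    random_slopes <- slope_terms
  }
  structure(list(direction = direction, test_terms = test_terms,
                 mains = mains,
                 two_way = if (include_interactions) two_way else character(0L),
                 three_way = if (include_interactions) three_way else character(0L),
                 controls = controls, ac_terms = c("ac_infant", "ac_male"),
                 random_intercepts = random_intercepts,
                 random_slopes = random_slopes,
                 response = response, offset_col = offset_col),
            class = "acglmm_spec")
}

#' Null counterpart of a model specification
#'
#' Drops every test predictor; AC terms, offset, controls and the random
#' structure are retained.
#'
#' @param spec an [model_spec()].
#' @return the null `acglmm_spec`.
#' @export
null_spec <- function(spec) {
  spec$test_terms <- character(0L)
  spec$two_way <- spec$three_way <- character(0L)
  # random slopes of test predictors are kept only if their term survives
  spec
}

build_formula <- function(spec, fixed_terms, with_ac = TRUE) {
  rhs <- fixed_terms
  if (with_ac) rhs <- c(rhs, spec$ac_terms)
  rhs <- c(rhs, spec$controls)
  if (length(rhs) == 0L) rhs <- "1"
  rand <- character(0L)
  if (length(spec$random_intercepts) > 0L) {
    rand <- sprintf("(1 | %s)", spec$random_intercepts)
  }
  if (length(spec$random_slopes) > 0L) {
    parts <- strsplit(spec$random_slopes, "\\|")
    rand <- c(rand, vapply(parts, function(p) {
      sprintf("(0 + %s | %s)", trimws(p[1L]), trimws(p[2L]))
    }, character(1L)))
  }
  off <- sprintf("offset(log(%s))", spec$offset_col)
  as.formula(paste(spec$response, "~",
                   paste(c(rhs, off, rand), collapse = " + ")))
}

#' Fit the binomial dyad-day model
#'
#' Fits the logit-link binomial model for a given set of fixed terms under
#' a specification's offset and random structure. With random terms the
#' marginal likelihood is integrated by the Laplace approximation
#' (`lme4::glmer`, bobyqa optimizer); without random terms an ordinary
#' logistic regression (`glm`) is used. Non-convergence is flagged on the
#' result, never raised.
#'
#' @param data assembled model table (or generator truth table).
#' @param spec an [model_spec()].
#' @param fixed_terms fixed-effect terms to include (default: the spec's
#'   test terms).
#' @param with_ac include the AC-term columns (they must exist in `data`;
#'   see [fit_ac_glmm()]).
#' @return list of class `acglmm_fit`: `coefficients` (data frame `term`,
#'   `estimate`, `se`), `logLik`, `n_par`, `converged`, `method`,
#'   `formula`, `model`, `spec`.
#' @export
fit_binomial <- function(data, spec, fixed_terms = spec$test_terms,
                         with_ac = FALSE) {
  # a control without variation in this dataset is dropped (it carries no
  # information and breaks the factor contrasts)
  keep <- vapply(spec$controls, function(cc) {
    !(cc %in% names(data)) || length(unique(data[[cc]])) > 1L
  }, logical(1L))
  spec$controls <- spec$controls[keep]
  fml <- build_formula(spec, fixed_terms, with_ac)
  has_rand <- length(spec$random_intercepts) + length(spec$random_slopes) > 0L
  if (has_rand) {
    for (g in spec$random_intercepts) data[[g]] <- factor(data[[g]])
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(fml, data = data, family = binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa",
                                               calc.derivs = FALSE))))
    sm <- summary(fit)$coefficients
    conv <- length(fit@optinfo$conv$lme4$messages %||% character(0L)) == 0L
    method <- "Laplace approximation (lme4::glmer)"
  } else {
    fit <- suppressWarnings(glm(fml, data = data, family = binomial(),
                                control = list(maxit = 100L)))
    sm <- summary(fit)$coefficients
    conv <- fit$converged
    method <- "ML (glm)"
  }
  ll <- logLik(fit)
  structure(list(
    coefficients = data.frame(term = rownames(sm), estimate = sm[, 1L],
                              se = sm[, 2L], row.names = NULL,
                              stringsAsFactors = FALSE),
    logLik = as.numeric(ll), n_par = attr(ll, "df"), converged = conv,
    method = method, formula = fml, model = fit, spec = spec),
    class = "acglmm_fit")
}

#' @export
print.acglmm_fit <- function(x, ...) {
  cat(sprintf("Binomial dyad-day model [%s]%s\n", x$method,
              if (x$converged) "" else " (did not converge)"))
  cat(sprintf("  logLik = %.2f on %d parameters\n", x$logLik, x$n_par))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Optimize the Gaussian AC-term bandwidth
#'
#' One-dimensional likelihood search for the kernel SD sigma of one AC key:
#' a log-spaced grid is scanned first, then the bracket around the best
#' grid point is refined by golden-section/parabolic search
#' (`stats::optimize`) on log(sigma). Each candidate sigma rebuilds the AC
#' column from the supplied base-model residuals and refits the model; the
#' likelihood maximized is that of the refitted model. When the likelihood
#' is flat in sigma (no temporal autocorrelation to absorb) the grid upper
#' bound is returned with `flat = TRUE`.
#'
#' @param data model table.
#' @param spec an [model_spec()].
#' @param key `"infant"` or `"male"` (which AC term to optimize).
#' @param resid base-model response-scale residuals.
#' @param fixed_terms fixed terms of the refitted model (default: test
#'   terms).
#' @param other_ac optional fixed values for the other key's AC column (kept
#'   in the model while this key's sigma is searched).
#' @param sigma_grid candidate bandwidths in days.
#' @param refine run the continuous refinement step (default TRUE).
#' @return list with `sigma`, `logLik`, `path` (grid log-likelihoods),
#'   `flat`.
#' @export
optimize_bandwidth <- function(data, spec, key = c("infant", "male"), resid,
                               fixed_terms = spec$test_terms,
                               other_ac = NULL,
                               sigma_grid = exp(seq(log(1), log(180),
                                                    length.out = 7L)),
                               refine = TRUE) {
  key <- match.arg(key)
  ac_col <- paste0("ac_", key)
  other_col <- setdiff(spec$ac_terms, ac_col)
  sp <- spec
  sp$ac_terms <- ac_col
  if (!is.null(other_ac)) {
    data[[other_col]] <- other_ac
    sp$ac_terms <- c(ac_col, other_col)
  }
  ll_at <- function(sigma) {
    data[[ac_col]] <- ac_term(data$day, data[[key]], resid, sigma)
    fit_binomial(data, sp, fixed_terms, with_ac = TRUE)$logLik
  }
  path <- vapply(sigma_grid, ll_at, numeric(1L))
  best <- which.max(path)
  flat <- (max(path) - min(path)) < 1e-4
  if (flat) {
    return(list(sigma = sigma_grid[length(sigma_grid)],
                logLik = path[length(path)], path = path, flat = TRUE))
  }
  sigma <- sigma_grid[best]
  ll <- path[best]
  if (refine) {
    lo <- if (best > 1L) sigma_grid[best - 1L] else sigma_grid[1L] / 2
    hi <- if (best < length(sigma_grid)) sigma_grid[best + 1L] else
      sigma_grid[best] * 2
    opt <- optimize(function(ls) ll_at(exp(ls)), interval = log(c(lo, hi)),
                    maximum = TRUE, tol = 0.05)
    if (opt$objective > ll) {
      sigma <- exp(opt$maximum)
      ll <- opt$objective
    }
  }
  list(sigma = sigma, logLik = ll, path = path, flat = flat)
}

#' Fit the dyad-day model with optimized AC terms
#'
#' The full fitting procedure: (1) fit the base model without AC terms;
#' (2) take its response-scale residuals; (3) optimize the infant AC
#' bandwidth; (4) holding the infant AC column fixed, optimize the male AC
#' bandwidth; (5) refit with both AC terms. The two bandwidths are
#' optimized sequentially (one pass each), each conditional on the other's
#' current term; residuals come from the base model throughout.
#'
#' @inheritParams optimize_bandwidth
#' @param fixed_terms fixed test terms (default: the spec's).
#' @return an `acglmm_fit` with extra fields `sigma` (named bandwidths),
#'   `base_fit`, `ac_flat` flags, and the AC columns attached to
#'   `$data`.
#' @export
fit_ac_glmm <- function(data, spec, fixed_terms = spec$test_terms,
                        sigma_grid = exp(seq(log(1), log(180),
                                             length.out = 7L)),
                        refine = TRUE) {
  base <- fit_binomial(data, spec, fixed_terms, with_ac = FALSE)
  r <- data[[spec$response]] - fitted(base$model)
  oi <- optimize_bandwidth(data, spec, "infant", r, fixed_terms,
                           sigma_grid = sigma_grid, refine = refine)
  data$ac_infant <- ac_term(data$day, data$infant, r, oi$sigma)
  om <- optimize_bandwidth(data, spec, "male", r, fixed_terms,
                           other_ac = data$ac_infant,
                           sigma_grid = sigma_grid, refine = refine)
  data$ac_male <- ac_term(data$day, data$male, r, om$sigma)
  fit <- fit_binomial(data, spec, fixed_terms, with_ac = TRUE)
  fit$sigma <- c(infant = oi$sigma, male = om$sigma)
  fit$ac_flat <- c(infant = oi$flat, male = om$flat)
  fit$base_fit <- base
  fit$data <- data
  fit
}

#' Likelihood ratio test of nested fits
#'
#' `chi2 = 2 (ll_full - ll_reduced)` (floored at 0), `df` the parameter
#' difference, p from the upper chi-square tail. Both fits must come from
#' the same likelihood method.
#'
#' @param full,reduced `acglmm_fit` objects (reduced nested in full).
#' @return list with `chisq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  df <- full$n_par - reduced$n_par
  if (df < 0L) stop_data("'reduced' has more parameters than 'full'")
  p <- if (df == 0L) {
    if (chisq <= 1e-8) 1 else NA_real_
  } else {
    pchisq(chisq, df, lower.tail = FALSE)
  }
  list(chisq = chisq, df = df, p = p)
}

#' Hierarchical pruning of non-significant interactions
#'
#' Tests each three-way interaction by LRT against the current model
#' without it (in declaration order, removals applied immediately), then
#' each remaining two-way likewise; a two-way contained in a retained
#' three-way is kept untested. Lower-order terms of retained interactions
#' are always kept, so the final model is hierarchical. AC columns must be
#' present in `data` (e.g. from [fit_ac_glmm()]`$data`) and are held fixed
#' during pruning.
#'
#' @param data model table with AC columns.
#' @param spec an [model_spec()].
#' @param alpha retention threshold (default 0.05).
#' @param with_ac include AC terms (default TRUE).
#' @return list with `final_terms`, `log` (data frame `term`, `tier`,
#'   `chisq`, `df`, `p`, `action`) and `final_fit`.
#' @export
prune_interactions <- function(data, spec, alpha = 0.05, with_ac = TRUE) {
  current <- spec$test_terms
  log_rows <- list()
  test_tier <- function(tier_terms, tier_name, current) {
    for (tm in tier_terms) {
      if (!(tm %in% current)) next
      if (tier_name == "two_way" &&
          any(vapply(intersect(spec$three_way, current), function(h) {
            all(strsplit(tm, ":")[[1L]] %in% strsplit(h, ":")[[1L]])
          }, logical(1L)))) {
        log_rows[[length(log_rows) + 1L]] <<- data.frame(
          term = tm, tier = tier_name, chisq = NA_real_, df = NA_integer_,
          p = NA_real_, action = "kept (within retained interaction)",
          stringsAsFactors = FALSE)
        next
      }
      f_full <- fit_binomial(data, spec, current, with_ac = with_ac)
      f_red <- fit_binomial(data, spec, setdiff(current, tm),
                            with_ac = with_ac)
      t <- lrt(f_full, f_red)
      keep <- !is.na(t$p) && t$p <= alpha
      if (!keep) current <- setdiff(current, tm)
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        term = tm, tier = tier_name, chisq = t$chisq, df = t$df, p = t$p,
        action = if (keep) "kept" else "removed", stringsAsFactors = FALSE)
    }
    current
  }
  current <- test_tier(spec$three_way, "three_way", current)
  current <- test_tier(spec$two_way, "two_way", current)
  list(final_terms = current,
       log = do.call(rbind, log_rows) %||%
         data.frame(term = character(0L)),
       final_fit = fit_binomial(data, spec, current, with_ac = with_ac))
}

#' Variance inflation factors of the fixed main effects
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` is from regressing predictor k
#' on the other main-effect predictors (interactions excluded, as their
#' collinearity with their own components is structural).
#'
#' @param data model table.
#' @param terms fixed-effect terms (interaction terms are filtered out).
#' @return named numeric vector of VIFs.
#' @export
vif_terms <- function(data, terms) {
  mains <- terms[!grepl(":", terms, fixed = TRUE)]
  if (length(mains) < 2L) stop_data("need >= 2 main-effect terms for VIF")
  mm <- stats::model.matrix(
    as.formula(paste("~", paste(mains, collapse = "+"))), data = data)
  mm <- mm[, -1L, drop = FALSE]
  vif <- vapply(seq_len(ncol(mm)), function(k) {
    r2 <- suppressWarnings(
      summary(lm(mm[, k] ~ mm[, -k, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-8) {
      stop_data("perfect collinearity involving '%s'", colnames(mm)[k])
    }
    1 / (1 - r2)
  }, numeric(1L))
  setNames(vif, colnames(mm))
}

#' Model stability under leave-one-level-out refits
#'
#' Refits the model excluding each level of the chosen grouping factors one
#' at a time and reports the change in every fixed-effect estimate,
#' flagging influential subjects/dyads.
#'
#' @param data model table (with AC columns if `with_ac`).
#' @param spec an [model_spec()].
#' @param fixed_terms fixed terms of the reference fit.
#' @param groups grouping factors to drop levels from (default: the spec's
#'   random intercepts that exist as columns).
#' @param with_ac include AC terms.
#' @return data frame with one row per (excluded level, term): `group`,
#'   `level`, `term`, `estimate`, `delta`.
#' @export
stability_check <- function(data, spec, fixed_terms = spec$test_terms,
                            groups = NULL, with_ac = FALSE) {
  if (is.null(groups)) {
    groups <- intersect(spec$random_intercepts, names(data))
  }
  ref <- fit_binomial(data, spec, fixed_terms, with_ac = with_ac)
  ref_est <- setNames(ref$coefficients$estimate, ref$coefficients$term)
  out <- list()
  for (g in groups) {
    for (lev in unique(as.character(data[[g]]))) {
      sub <- data[as.character(data[[g]]) != lev, , drop = FALSE]
      f <- tryCatch(fit_binomial(sub, spec, fixed_terms, with_ac = with_ac),
                    error = function(e) NULL)
      if (is.null(f)) next
      est <- setNames(f$coefficients$estimate, f$coefficients$term)
      shared <- intersect(names(ref_est), names(est))
      out[[length(out) + 1L]] <- data.frame(
        group = g, level = lev, term = shared, estimate = est[shared],
        delta = est[shared] - ref_est[shared], row.names = NULL,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
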