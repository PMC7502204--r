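# Adjusted associations of the Healthy Diet Score with changes in
# cardiometabolic factors: nested adjustment models with a class-level
# random intercept, trend tests, Benjamini-Hochberg FDR control, Bonferroni
# pairwise comparisons, and moderation analysis.

#' Covariate sets of the nested adjustment models
#'
#' * `M1`: age, sex, and the outcome's baseline value.
#' * `M2`: M1 plus intervention arm, grade, puberty, baseline BMI, physical
#'   activity (MET), and baseline intakes of energy, fiber, vegetables,
#'   fruit, pork, and nuts/legumes.
#' * `M3`: M2 plus birthweight, breastfeeding, household income, and
#'   parental BMI and education categories ("Missing" kept as a level).
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param outcome Outcome measure name (determines the baseline-value
#'   column `base_<outcome>`; for the BMI outcome the redundant baseline-BMI
#'   adjuster of M2 is omitted).
#' @return Character vector of column names.
#' @export
model_covariates <- function(model = c("M1", "M2", "M3"), outcome = "cmrs") {
  model <- match.arg(model)
  m1 <- c(paste0("base_", outcome), "age", "sex")
  m2 <- c(m1, "intervention", "grade", "puberty",
          if (outcome != "bmi") "bmi_baseline",
          "met", "energy", "fiber", "veg_intake", "fruit_intake",
          "pork_intake", "nuts_intake")
  m3 <- c(m2, "birthweight", "breastfeeding", "income", "mother_bmi",
          "father_bmi", "mother_edu", "father_edu")
  switch(model, M1 = m1, M2 = m2, M3 = m3)
}

#' Specification for one association fit
#'
#' @param model Adjustment model id (`"M1"`, `"M2"`, `"M3"`).
#' @param outcome Measure whose change is the response (e.g. `"cmrs"`,
#'   `"bmi"`); columns `delta_<outcome>` and `base_<outcome>` must exist.
#' @param exposure `"hds_bands"` (six bands, lowest as reference),
#'   `"hds_continuous"`, or `"delta_hds"`.
#' @param fdr_q FDR level for families of outcomes (default 0.05).
#' @return A `model_spec` list.
#' @export
model_spec <- function(model = c("M1", "M2", "M3"), outcome = "cmrs",
                       exposure = c("hds_bands", "hds_continuous",
                                    "delta_hds"),
                       fdr_q = 0.05) {
  structure(list(model = match.arg(model), outcome = outcome,
                 exposure = match.arg(exposure), fdr_q = fdr_q),
            class = "model_spec")
}

exposure_column <- function(exposure) {
  switch(exposure, hds_bands = "hds_band", hds_continuous = "hds",
         delta_hds = "delta_hds")
}

# Linear model with a class-level random intercept; falls back to a plain
# fixed-effects fit when fewer than two clusters remain. Complete-case on
# the modelled continuous variables ("Missing" factor levels are data, not
# missingness). Errors on rank-deficient designs, naming aliased columns.
fit_mixed <- function(data, outcome, exposure, covariates,
                      cluster = "class_id") {
  require_columns(data, unique(c(outcome, exposure, covariates, cluster)),
                  "analysis data")
  used <- unique(c(outcome, exposure, covariates))
  df <- data[stats::complete.cases(data[, used]), , drop = FALSE]
  abort_if(nrow(df) <= length(used) + 2, "too few complete cases to fit")
  abort_if(length(unique(df[[exposure]])) < 2,
           "exposure '", exposure, "' is constant: no contrast to estimate")
  df <- droplevels(df)
  # unit-scale numeric covariates (exposure and outcome untouched): their
  # coefficients are nuisance parameters and raw scales (kcal, MET) are
  # poorly conditioned next to z-scored outcomes
  for (cv in setdiff(covariates, exposure)) {
    if (is.numeric(df[[cv]]) && stats::sd(df[[cv]]) > 0) {
      df[[cv]] <- as.numeric(scale(df[[cv]]))
    }
  }
  fixed <- stats::reformulate(c(exposure, covariates), response = outcome)
  mm <- stats::model.matrix(fixed, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  n_clusters <- length(unique(df[[cluster]]))
  if (n_clusters >= 2) {
    form <- stats::as.formula(paste(
      outcome, "~", paste(c(exposure, covariates), collapse = " + "),
      "+ (1 |", cluster, ")"))
    fit <- lme4::lmer(form, data = df, REML = TRUE,
                      control = lme4::lmerControl(
                        calc.derivs = FALSE,
                        check.conv.singular = "ignore"))
    coefs <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
  } else {
    warning("fewer than 2 clusters; falling back to a fixed-effects fit",
            call. = FALSE)
    fit <- stats::lm(fixed, data = df)
    coefs <- stats::coef(fit)
    V <- stats::vcov(fit)
  }
  list(coef = coefs, vcov = V, n = nrow(df), n_clusters = n_clusters,
       data = df, model = fit, mixed = n_clusters >= 2)
}

# Wald inference with the normal approximation (large-n)
wald_row <- function(coefs, V, term) {
  beta <- coefs[[term]]
  se <- sqrt(V[term, term])
  z <- beta / se
  c(beta = beta, se = se, ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
    p = 2 * stats::pnorm(-abs(z)))
}

#' Fit one adjusted association
#'
#' Linear mixed model of the change score on the exposure and the model's
#' covariates with a random intercept for class. Band exposures are coded
#' against the lowest band; the trend p-value comes from refitting with the
#' band index as a continuous term. Confidence intervals use the normal
#' approximation.
#'
#' @param data Analysis-ready table (see [prepare_analysis_data()] or
#'   [simulate_band_cohort()]).
#' @param spec A [model_spec()].
#' @param trend Compute the band-index trend test (default `TRUE`; only
#'   relevant for band exposures, where it costs a second model fit).
#' @return An `assoc_result`: list with `estimates` (one row per exposure
#'   level or term: `beta`, `se`, `ci_lo`, `ci_hi`, `p`, `n`), `p_trend`,
#'   `n`, `n_clusters` and the fitted coefficient/vcov pair.
#' @export
fit_association <- function(data, spec, trend = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  outcome_col <- paste0("delta_", spec$outcome)
  covs <- model_covariates(spec$model, spec$outcome)
  exp_col <- exposure_column(spec$exposure)
  fit <- fit_mixed(data, outcome_col, exp_col, covs)

  if (spec$exposure == "hds_bands") {
    levs <- levels(fit$data[[exp_col]])
    terms <- paste0(exp_col, levs[-1])
    n_by <- table(fit$data[[exp_col]])
    est <- rbind(
      c(beta = 0, se = 0, ci_lo = 0, ci_hi = 0, p = NA_real_),
      t(vapply(terms, function(tm) wald_row(fit$coef, fit$vcov, tm),
               numeric(5))))
    estimates <- tibble::tibble(level = levs, as.data.frame(est),
                                n = as.integer(n_by[levs]))
    p_trend <- if (trend) {
      trend_df <- fit$data
      trend_df$band_index <- as.numeric(trend_df[[exp_col]])
      tfit <- fit_mixed(trend_df, outcome_col, "band_index", covs)
      wald_row(tfit$coef, tfit$vcov, "band_index")[["p"]]
    } else NA_real_
  } else {
    row <- wald_row(fit$coef, fit$vcov, exp_col)
    estimates <- tibble::tibble(level = exp_col, as.data.frame(t(row)),
                                n = fit$n)
    p_trend <- row[["p"]]
  }
  structure(list(outcome = spec$outcome, model = spec$model,
                 exposure = spec$exposure, estimates = estimates,
                 p_trend = p_trend, n = fit$n, n_clusters = fit$n_clusters,
                 coef = fit$coef, vcov = fit$vcov, mixed = fit$mixed,
                 band_levels = if (spec$exposure == "hds_bands")
                   levels(fit$data[[exp_col]])),
            class = "assoc_result")
}

#' Benjamini-Hochberg step-up decisions
#'
#' Sorts the p-values ascending, finds the largest `k` with
#' `p(k) <= k * q / m`, and rejects the `k` smallest hypotheses. Also
#' reports the data-dependent significance cutoff `p(k)` (0 when nothing is
#' rejected), the quantity reported alongside FDR-controlled tables.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical, original order), `cutoff`, and
#'   `n_rejected`.
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  abort_if(any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1),
           "p-values must lie in [0, 1]")
  m <- length(pvalues)
  ord <- order(pvalues)
  sorted <- pvalues[ord]
  ok <- which(sorted <= seq_len(m) * q / m)
  k <- if (length(ok)) max(ok) else 0L
  cutoff <- if (k > 0) sorted[k] else 0
  list(reject = pvalues <= cutoff & k > 0, cutoff = cutoff,
       n_rejected = as.integer(k))
}

#' Bonferroni-adjusted pairwise band comparisons
#'
#' All pairwise contrasts between exposure bands from a fitted band model;
#' raw Wald p-values are multiplied by the number of comparisons
#' (`choose(B, 2)`) and capped at 1.
#'
#' @param result An `assoc_result` with a band exposure.
#' @return Tibble with `band_a`, `band_b`, `diff`, `se`, `p_raw`, `p_adj`.
#' @export
pairwise_bonferroni <- function(result) {
  abort_if(is.null(result$band_levels), "result does not have a band exposure")
  levs <- result$band_levels
  terms <- c(NA, paste0("hds_band", levs[-1]))  # reference has beta 0, var 0
  B <- length(levs)
  get_beta <- function(i) if (is.na(terms[i])) 0 else result$coef[[terms[i]]]
  get_v <- function(i, j) {
    if (is.na(terms[i]) || is.na(terms[j])) 0 else
      result$vcov[terms[i], terms[j]]
  }
  pairs <- utils::combn(B, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(kk) {
    i <- pairs[1, kk]; j <- pairs[2, kk]
    diff <- get_beta(j) - get_beta(i)
    v <- get_v(i, i) + get_v(j, j) - 2 * get_v(i, j)
    se <- sqrt(v)
    p <- 2 * stats::pnorm(-abs(diff / se))
    tibble::tibble(band_a = levs[i], band_b = levs[j], diff = diff, se = se,
                   p_raw = p, p_adj = pmin(1, p * m))
  })
  dplyr::bind_rows(rows)
}

#' Moderation of the score-outcome association
#'
#' Adds a product term between the continuous score and a categorical
#' modifier, tests the interaction block with a Wald chi-square, and reports
#' per-stratum score slopes with confidence intervals. Strata without
#' exposure variation are omitted with a warning.
#'
#' @param data Analysis-ready table.
#' @param modifier Name of a categorical column (e.g. `"mother_edu"`).
#' @param model Adjustment model id (the modifier itself is removed from the
#'   covariate set).
#' @param outcome Outcome measure (default `"cmrs"`).
#' @return List with `interaction_p`, `interaction_df`, and `strata`
#'   (tibble of per-level slopes).
#' @export
moderation <- function(data, modifier, model = "M3", outcome = "cmrs") {
  abort_if(!modifier %in% names(data), "modifier column not found")
  covs <- setdiff(model_covariates(model, outcome), modifier)
  outcome_col <- paste0("delta_", outcome)
  df <- tibble::as_tibble(data)
  df[[modifier]] <- droplevels(factor(df[[modifier]]))

  used <- unique(c(outcome_col, "hds", covs, modifier))
  cc <- df[stats::complete.cases(df[, used]), , drop = FALSE]
  for (cv in covs) {
    if (is.numeric(cc[[cv]]) && stats::sd(cc[[cv]]) > 0) {
      cc[[cv]] <- as.numeric(scale(cc[[cv]]))
    }
  }
  form <- stats::as.formula(paste(
    outcome_col, "~ hds *", modifier, "+",
    paste(covs, collapse = " + "), "+ (1 | class_id)"))
  fit <- lme4::lmer(form, data = cc, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular = "ignore"))
  coefs <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  int_terms <- grep(paste0("^hds:", modifier), names(coefs), value = TRUE)
  b <- coefs[int_terms]
  W <- as.numeric(t(b) %*% solve(V[int_terms, int_terms, drop = FALSE]) %*% b)
  interaction_p <- stats::pchisq(W, df = length(int_terms),
                                 lower.tail = FALSE)

  strata <- lapply(levels(cc[[modifier]]), function(lev) {
    sub <- cc[cc[[modifier]] == lev, , drop = FALSE]
    if (length(unique(sub$hds)) < 2) {
      warning("stratum '", lev, "' has no exposure variation; omitted",
              call. = FALSE)
      return(NULL)
    }
    sfit <- fit_mixed(sub, outcome_col, "hds", covs)
    row <- wald_row(sfit$coef, sfit$vcov, "hds")
    tibble::tibble(stratum = lev, n = sfit$n, slope = row[["beta"]],
                   se = row[["se"]], ci_lo = row[["ci_lo"]],
                   ci_hi = row[["ci_hi"]], p = row[["p"]])
  })
  list(interaction_p = interaction_p, interaction_df = length(int_terms),
       strata = dplyr::bind_rows(strata))
}

#' Repeat an association analysis in a subset
#'
#' @param data Analysis-ready table with an `intervention` column.
#' @param spec A [model_spec()].
#' @param subset `"all"`, `"control"` or `"intervention"`.
#' @return An `assoc_result`.
#' @export
sensitivity_subset <- function(data, spec,
                               subset = c("all", "control", "intervention")) {
  subset <- match.arg(subset)
  if (subset == "all") return(fit_association(data, spec))
  data <- data[data$intervention == subset, , drop = FALSE]
  abort_if(nrow(data) == 0, "empty subset: ", subset)
  # refit with the intervention covariate removed
  covs <- setdiff(model_covariates(spec$model, spec$outcome), "intervention")
  outcome_col <- paste0("delta_", spec$outcome)
  exp_col <- exposure_column(spec$exposure)
  fit <- fit_mixed(data, outcome_col, exp_col, covs)
  row <- if (spec$exposure == "hds_bands") {
    levs <- levels(fit$data[[exp_col]])
    terms <- paste0(exp_col, levs[-1])
    est <- rbind(c(beta = 0, se = 0, ci_lo = 0, ci_hi = 0, p = NA_real_),
                 t(vapply(terms, function(tm) wald_row(fit$coef, fit$vcov, tm),
                          numeric(5))))
    tibble::tibble(level = levs, as.data.frame(est),
                   n = as.integer(table(fit$data[[exp_col]])[levs]))
  } else {
    r <- wald_row(fit$coef, fit$vcov, exp_col)
    tibble::tibble(level = exp_col, as.data.frame(t(r)), n = fit$n)
  }
  p_trend <- if (spec$exposure == "hds_bands") {
    trend_df <- fit$data
    trend_df$band_index <- as.numeric(trend_df[[exp_col]])
    tfit <- fit_mixed(trend_df, outcome_col, "band_index", covs)
    wald_row(tfit$coef, tfit$vcov, "band_index")[["p"]]
  } else row$p[1]
  structure(list(outcome = spec$outcome, model = spec$model,
                 exposure = spec$exposure, estimates = row,
                 p_trend = p_trend, n = fit$n, n_clusters = fit$n_clusters,
                 coef = fit$coef, vcov = fit$vcov, mixed = fit$mixed,
                 band_levels = if (spec$exposure == "hds_bands")
                   levels(fit$data[[exp_col]]),
                 subset = subset),
            class = "assoc_result")
}

#' Fit a family of outcomes and control the FDR
#'
#' Fits the same exposure/model specification across a family of outcomes
#' and applies the step-up FDR rule to the trend p-values.
#'
#' @param data Analysis-ready table.
#' @param outcomes Character vector of outcome measures.
#' @param model,exposure,fdr_q Passed to [model_spec()].
#' @return List with `results` (long tibble over outcomes and levels),
#'   `p_trend` (named), and `bh` (the [bh_adjust()] output).
#' @export
run_associations <- function(data, outcomes, model = "M3",
                             exposure = "hds_bands", fdr_q = 0.05) {
  fits <- lapply(outcomes, function(oc) {
    fit_association(data, model_spec(model, oc, exposure, fdr_q))
  })
  names(fits) <- outcomes
  p_trend <- vapply(fits, `[[`, numeric(1), "p_trend")
  bh <- bh_adjust(p_trend, q = fdr_q)
  results <- dplyr::bind_rows(lapply(fits, function(f) {
    dplyr::mutate(f$estimates, outcome = f$outcome, model = f$model,
                  exposure = f$exposure, p_trend = f$p_trend,
                  .before = 1)
  }))
  results$fdr_significant <- bh$reject[match(results$outcome, outcomes)]
  list(results = results, p_trend = p_trend, bh = bh, fits = fits)
}

#' Empirical FDR of the step-up procedure under a planted mixture
#'
#' Simulates replicate families of two-sample comparisons (a fixed number of
#' true nulls plus alternatives with a given standardized mean difference),
#' computes Welch t-test p-values, applies [bh_adjust()] at level `q` to
#' each family, and returns the mean false discovery proportion (0 when a
#' family rejects nothing).
#'
#' @param n_replicates Number of replicate families (default 2000).
#' @param m_null,m_alt True nulls and alternatives per family (40 and 10).
#' @param effect Standardized mean difference under the alternative (0.5).
#' @param n_per_arm Observations per arm of each test (200).
#' @param q FDR level (0.05).
#' @param seed Seed.
#' @return List with `fdr` (proportion), `fdr_pct`, `power`, and
#'   `n_replicates`.
#' @export
simulate_fdr <- function(n_replicates = 2000, m_null = 40, m_alt = 10,
                         effect = 0.5, n_per_arm = 200, q = 0.05, seed = 1L) {
  set.seed(seed)
  m <- m_null + m_alt
  is_alt <- rep(c(FALSE, TRUE), c(m_null, m_alt))
  deltas <- ifelse(is_alt, effect, 0)
  chunk <- 100L
  fdp <- numeric(n_replicates)
  power <- numeric(n_replicates)
  done <- 0L
  while (done < n_replicates) {
    nb <- min(chunk, n_replicates - done)
    k <- nb * m
    x <- matrix(stats::rnorm(n_per_arm * k), n_per_arm, k)
    y <- matrix(stats::rnorm(n_per_arm * k,
                             mean = rep(rep(deltas, nb), each = n_per_arm)),
                n_per_arm, k)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- (colMeans(x^2) - mx^2) * n_per_arm / (n_per_arm - 1)
    vy <- (colMeans(y^2) - my^2) * n_per_arm / (n_per_arm - 1)
    se2 <- vx / n_per_arm + vy / n_per_arm
    tstat <- (my - mx) / sqrt(se2)
    df <- se2^2 / ((vx / n_per_arm)^2 / (n_per_arm - 1) +
                     (vy / n_per_arm)^2 / (n_per_arm - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    pm <- matrix(p, m, nb)
    for (b in seq_len(nb)) {
      dec <- bh_adjust(pm[, b], q = q)
      R <- sum(dec$reject)
      V <- sum(dec$reject & !is_alt)
      fdp[done + b] <- if (R > 0) V / R else 0
      power[done + b] <- sum(dec$reject & is_alt) / m_alt
    }
    done <- done + nb
  }
  list(fdr = mean(fdp), fdr_pct = 100 * mean(fdp), power = mean(power),
       n_replicates = n_replicates)
}

#' Forest plot of band associations
#'
#' @param results Long results tibble from [run_associations()].
#' @return A ggplot object.
#' @export
plot_associations <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$beta, y = .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo,
                                         xmax = .data$ci_hi), height = 0.2) +
    ggplot2::facet_wrap(~outcome, scales = "free_x") +
    ggplot2::labs(x = "Adjusted change (95% CI)", y = "Diet score band") +
    ggplot2::theme_minimal()
}
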