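# Ranking dietary determinants of the change in CMRS: three model families
# (elastic-net linear regression, random forest, gradient boosting) fitted
# on a 50/50 split with grid search under 5-fold cross-validation, compared
# on the held-out half, and the winner's variable importances normalized to
# percentage contributions.

#' Ranking configuration
#'
#' @param test_fraction Fraction of children held out for model comparison
#'   (default 0.5).
#' @param seed Seed controlling the split, fold assignment, tree growing and
#'   permutation draws.
#' @param n_trees Trees for the forest and boosting rounds (default 500).
#' @param cv_folds Cross-validation folds for the hyperparameter grids
#'   (default 5).
#' @param grids Per-family hyperparameter grids; see
#'   [default_ranking_grids()].
#' @param importance `"permutation"` (held-out permutation importance;
#'   default, comparable across families) or `"impurity"` (forest only).
#' @param n_permutations Permutations averaged per predictor.
#' @param cv_trees Forest size during grid search; the selected
#'   hyperparameters are refitted with the full `n_trees` (cross-validated
#'   R-squared is insensitive to forest size beyond a few hundred trees, so
#'   the grid is scored on a thinned forest).
#' @return A `ranking_config` list.
#' @export
ranking_config <- function(test_fraction = 0.5, seed = 1L, n_trees = 500,
                           cv_folds = 5, grids = default_ranking_grids(),
                           importance = c("permutation", "impurity"),
                           n_permutations = 3, cv_trees = 100) {
  abort_if(test_fraction <= 0 || test_fraction >= 1,
           "test_fraction must lie strictly between 0 and 1")
  abort_if(any(vapply(grids, nrow, integer(1)) == 0), "grids must be non-empty")
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 n_trees = n_trees, cv_folds = cv_folds, grids = grids,
                 importance = match.arg(importance),
                 n_permutations = n_permutations,
                 cv_trees = min(cv_trees, n_trees)),
            class = "ranking_config")
}

#' Default hyperparameter grids
#'
#' Compact grids: the elastic net searches mixing parameter alpha (L1 vs L2)
#' and penalty strength lambda; the forest searches variables per split and
#' tree depth (0 = unlimited); boosting searches depth, learning rate and
#' row/column subsampling.
#'
#' @return Named list of data frames (`linear`, `forest`, `boosting`).
#' @export
default_ranking_grids <- function() {
  list(
    linear = expand.grid(alpha = c(0, 0.5, 1),
                         lambda = c(0.001, 0.01, 0.1)),
    forest = expand.grid(mtry = c(5, 9, 13), max_depth = c(0, 8)),
    boosting = expand.grid(max_depth = c(2, 3), eta = c(0.05, 0.1),
                           subsample = 0.8, colsample = 0.8)
  )
}

#' Split a cohort into training and testing halves
#'
#' Seeded random partition of the rows at `test_fraction`.
#'
#' @param n Number of children (or a data frame, in which case its row
#'   count).
#' @param config A [ranking_config()].
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(n, config = ranking_config()) {
  if (is.data.frame(n) || is.matrix(n)) n <- nrow(n)
  abort_if(n < 2, "need at least 2 children to split")
  abort_if(floor(n * (1 - config$test_fraction)) < config$cv_folds,
           "training half too small for ", config$cv_folds, "-fold CV")
  set.seed(derive_seed(config$seed, 1L))
  test <- sort(sample.int(n, size = round(n * config$test_fraction)))
  list(train = setdiff(seq_len(n), test), test = test)
}

r_squared <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)

fit_engine <- function(x, y, family, params, n_trees, seed) {
  switch(family,
    linear = glmnet::glmnet(x, y, alpha = params$alpha,
                            lambda = params$lambda, family = "gaussian"),
    forest = ranger::ranger(
      x = x, y = y, num.trees = n_trees, mtry = params$mtry,
      max.depth = params$max_depth, seed = seed, num.threads = 1,
      importance = "impurity"),
    boosting = xgboost::xgb.train(
      params = list(max_depth = params$max_depth, eta = params$eta,
                    subsample = params$subsample,
                    colsample_bytree = params$colsample,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = n_trees,
      verbose = 0)
  )
}

predict_engine <- function(fit, family, x, params = NULL) {
  switch(family,
    linear = as.numeric(stats::predict(fit, newx = x, s = params$lambda)),
    forest = stats::predict(fit, data = x, num.threads = 1)$predictions,
    boosting = stats::predict(fit, xgboost::xgb.DMatrix(x))
  )
}

#' Fit one model family with grid search and cross-validation
#'
#' Scores every grid point by 5-fold cross-validated R-squared on the
#' training half, retains the best, refits it on the full training half, and
#' logs the train-vs-CV gap as an overfitting check.
#'
#' @param x_train Numeric matrix of the 26 baseline intakes (g/100 kcal).
#' @param y_train Change in the composite risk score.
#' @param family `"linear"`, `"forest"` or `"boosting"`.
#' @param config A [ranking_config()].
#' @return A `family_fit`: list with the fitted model, `best_params`,
#'   `cv_r2`, `train_r2`, and the full `cv_table`.
#' @export
fit_family <- function(x_train, y_train, family = c("linear", "forest",
                                                    "boosting"),
                       config = ranking_config()) {
  family <- match.arg(family)
  abort_if(stats::sd(y_train) == 0, "outcome has zero variance")
  x_train <- as.matrix(x_train)
  n <- nrow(x_train)
  abort_if(n < config$cv_folds, "fewer children than CV folds")
  grid <- config$grids[[family]]
  set.seed(derive_seed(config$seed, 2L))
  folds <- sample(rep_len(seq_len(config$cv_folds), n))
  sst <- sum((y_train - mean(y_train))^2)

  cv_r2 <- vapply(seq_len(nrow(grid)), function(i) {
    params <- as.list(grid[i, , drop = FALSE])
    sse <- 0
    grid_trees <- if (family == "forest") config$cv_trees else config$n_trees
    for (f in seq_len(config$cv_folds)) {
      hold <- folds == f
      fit <- fit_engine(x_train[!hold, , drop = FALSE], y_train[!hold],
                        family, params, grid_trees,
                        derive_seed(config$seed, 100L + f))
      pred <- predict_engine(fit, family, x_train[hold, , drop = FALSE],
                             params)
      sse <- sse + sum((y_train[hold] - pred)^2)
    }
    1 - sse / sst
  }, numeric(1))

  best <- which.max(cv_r2)
  best_params <- as.list(grid[best, , drop = FALSE])
  model <- fit_engine(x_train, y_train, family, best_params, config$n_trees,
                      derive_seed(config$seed, 3L))
  train_r2 <- r_squared(y_train,
                        predict_engine(model, family, x_train, best_params))
  structure(list(family = family, model = model, best_params = best_params,
                 cv_r2 = cv_r2[best], train_r2 = train_r2,
                 overfit_gap = train_r2 - cv_r2[best],
                 cv_table = cbind(grid, cv_r2 = cv_r2)),
            class = "family_fit")
}

# Permutation importance on held-out data: mean increase in test MSE when a
# predictor's column is shuffled, averaged over n_permutations draws.
permutation_importance <- function(fit, x_test, y_test, config) {
  x_test <- as.matrix(x_test)
  base_pred <- predict_engine(fit$model, fit$family, x_test, fit$best_params)
  base_mse <- mean((y_test - base_pred)^2)
  set.seed(derive_seed(config$seed, 4L))
  imp <- vapply(seq_len(ncol(x_test)), function(g) {
    mean(vapply(seq_len(config$n_permutations), function(b) {
      xp <- x_test
      xp[, g] <- xp[sample.int(nrow(xp)), g]
      mean((y_test - predict_engine(fit$model, fit$family, xp,
                                    fit$best_params))^2)
    }, numeric(1))) - base_mse
  }, numeric(1))
  stats::setNames(imp, colnames(x_test))
}

normalize_contributions <- function(raw) {
  raw <- pmax(raw, 0)
  if (sum(raw) == 0) {
    warning("all importances non-positive; contributions set uniform",
            call. = FALSE)
    raw <- rep(1, length(raw))
  }
  100 * raw / sum(raw)
}

#' Compare fitted families on the test half and rank food groups
#'
#' The winner is the family with the highest held-out R-squared (ties broken
#' in the fixed order linear < forest < boosting). The winner's raw
#' importances (held-out permutation importance by default, floored at zero)
#' are normalized to percentage contributions summing to 100, and groups are
#' ranked by contribution with ties broken by the fixed group order.
#'
#' @param fits List of `family_fit` objects (at least one).
#' @param x_test,y_test Held-out intakes and change scores.
#' @param config A [ranking_config()].
#' @return An `importance_result`: list with `family` (winner), `test_r2`
#'   (named, all families), `contributions` (named percentages),
#'   `ranking` (groups by descending contribution), `selected_hyperparams`,
#'   and per-family diagnostics.
#' @export
compare_and_rank <- function(fits, x_test, y_test,
                             config = ranking_config()) {
  abort_if(length(fits) == 0, "need at least one fitted family")
  x_test <- as.matrix(x_test)
  fam_order <- c("linear", "forest", "boosting")
  fits <- fits[order(match(vapply(fits, `[[`, "", "family"), fam_order))]
  test_r2 <- vapply(fits, function(f) {
    r_squared(y_test, predict_engine(f$model, f$family, x_test,
                                     f$best_params))
  }, numeric(1))
  names(test_r2) <- vapply(fits, `[[`, "", "family")
  winner <- fits[[which.max(test_r2)]]  # which.max takes the first on ties

  raw <- if (config$importance == "impurity") {
    abort_if(winner$family != "forest",
             "impurity importance is only available for the forest")
    winner$model$variable.importance
  } else {
    permutation_importance(winner, x_test, y_test, config)
  }
  contributions <- normalize_contributions(raw[colnames(x_test)])
  ord <- order(-contributions, match(names(contributions), food_groups()))
  structure(list(family = winner$family, test_r2 = test_r2,
                 contributions = contributions,
                 ranking = names(contributions)[ord],
                 selected_hyperparams = winner$best_params,
                 fits = fits),
            class = "importance_result")
}

#' Select the leading determinants
#'
#' Top `k` groups by contribution, descending, ties broken by the fixed
#' group order.
#'
#' @param result An `importance_result`.
#' @param k How many groups (default 9).
#' @return Character vector of length `k`.
#' @export
select_leading <- function(result, k = 9) {
  abort_if(k > length(result$ranking), "k exceeds the number of groups")
  result$ranking[seq_len(k)]
}

#' Rank dietary determinants end-to-end
#'
#' Convenience wrapper: splits the cohort, fits the three families on the
#' training half, and compares them on the testing half.
#'
#' @param features Matrix or data frame of the 26 baseline intakes.
#' @param outcome Change in the composite risk score.
#' @param config A [ranking_config()].
#' @param families Families to fit.
#' @return An `importance_result`.
#' @export
rank_determinants <- function(features, outcome, config = ranking_config(),
                              families = c("linear", "forest", "boosting")) {
  x <- as.matrix(features)
  keep <- !is.na(outcome)
  x <- x[keep, , drop = FALSE]
  y <- outcome[keep]
  idx <- split_cohort(nrow(x), config)
  fits <- lapply(families, function(fam) {
    fit_family(x[idx$train, , drop = FALSE], y[idx$train], fam, config)
  })
  compare_and_rank(fits, x[idx$test, , drop = FALSE], y[idx$test], config)
}

#' Write an importance result to JSON and CSV
#'
#' @param result An `importance_result`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return `result`, invisibly.
#' @export
write_importance <- function(result, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(winner = result$family, test_r2 = as.list(result$test_r2),
           selected_hyperparams = result$selected_hyperparams,
           contributions = as.list(result$contributions)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      tibble::tibble(rank = seq_along(result$ranking),
                     group = result$ranking,
                     contribution_pct =
                       as.numeric(result$contributions[result$ranking])),
      csv_path, row.names = FALSE)
  }
  invisible(result)
}

#' Bar chart of percentage contributions
#'
#' @param result An `importance_result`.
#' @param k Show the top `k` groups.
#' @return A ggplot object.
#' @export
plot_contributions <- function(result, k = 9) {
  df <- tibble::tibble(
    group = factor(result$ranking[seq_len(k)],
                   levels = rev(result$ranking[seq_len(k)])),
    contribution = as.numeric(result$contributions[result$ranking[seq_len(k)]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution, y = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Contribution (% of total variance attribution)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
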