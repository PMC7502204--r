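mk_xy <- function(n, seed = 1, beta = NULL, noise = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 26), n, 26, dimnames = list(NULL, food_groups()))
  if (is.null(beta)) beta <- numeric(26)
  y <- as.numeric(x %*% beta) + rnorm(n, 0, noise)
  list(x = x, y = y)
}

test_that("the cohort split is a seeded partition", {
  cfg <- ranking_config(seed = 5)
  s1 <- split_cohort(100, cfg)
  s2 <- split_cohort(100, cfg)
  expect_identical(s1, s2)
  expect_length(s1$test, 50)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_setequal(c(s1$train, s1$test), 1:100)
  s3 <- split_cohort(100, ranking_config(seed = 6))
  expect_false(identical(s1$test, s3$test))
  expect_error(split_cohort(6, cfg), "too small")
  expect_error(ranking_config(test_fraction = 1), "strictly between")
})

test_that("a noiseless linear signal is fit nearly perfectly", {
  beta <- numeric(26); beta[1] <- 2
  d <- mk_xy(300, seed = 2, beta = beta, noise = 0)
  fit <- fit_family(d$x, d$y, "linear", ranking_config(seed = 2))
  expect_gt(fit$cv_r2, 0.99)
  expect_gt(fit$train_r2, 0.99)
})

test_that("pure-noise outcomes give near-zero held-out performance", {
  d <- mk_xy(400, seed = 3)
  cfg <- ranking_config(seed = 3)
  idx <- split_cohort(400, cfg)
  fits <- lapply(c("linear", "forest", "boosting"), function(fam) {
    fit_family(d$x[idx$train, ], d$y[idx$train], fam, cfg)
  })
  res <- compare_and_rank(fits, d$x[idx$test, ], d$y[idx$test], cfg)
  expect_true(all(res$test_r2 < 0.05))
  expect_equal(sum(res$contributions), 100, tolerance = 1e-6)
})

test_that("degenerate outcomes are rejected", {
  d <- mk_xy(50, seed = 4)
  expect_error(fit_family(d$x, rep(1, 50), "linear", ranking_config()),
               "zero variance")
})

test_that("contributions normalize to percentages and respect scaling", {
  raw <- c(2, 1, 1, rep(0, 23))
  norm <- dietcmr:::normalize_contributions(raw)
  expect_equal(norm[1:3], c(50, 25, 25))
  expect_equal(sum(norm), 100)
  expect_equal(dietcmr:::normalize_contributions(raw * 37.5), norm)
  # negative importances floor at zero before normalization
  expect_equal(dietcmr:::normalize_contributions(c(3, -5, 1, rep(0, 23)))[1:2],
               c(75, 0))
})

test_that("a single fitted family wins by default", {
  beta <- numeric(26); beta[2] <- 0.5
  d <- mk_xy(400, seed = 5, beta = beta)
  cfg <- ranking_config(seed = 5)
  idx <- split_cohort(400, cfg)
  fit <- fit_family(d$x[idx$train, ], d$y[idx$train], "linear", cfg)
  res <- compare_and_rank(list(fit), d$x[idx$test, ], d$y[idx$test], cfg)
  expect_equal(res$family, "linear")
  expect_equal(res$ranking[1], food_groups()[2])
})

test_that("leading-group selection is a stable top-k", {
  contrib <- stats::setNames(rep(0, 26), food_groups())
  contrib[c("seafood", "rice", "wheat")] <- c(50, 30, 20)
  res <- structure(list(contributions = contrib,
                        ranking = c(c("seafood", "rice", "wheat"),
                                    setdiff(food_groups(),
                                            c("seafood", "rice", "wheat")))),
                   class = "importance_result")
  expect_equal(select_leading(res, 3), c("seafood", "rice", "wheat"))
  expect_length(select_leading(res, 26), 26)
  expect_error(select_leading(res, 27), "exceeds")
  # zero-contribution ties fall back to the frozen group order
  expect_equal(select_leading(res, 4)[4],
               setdiff(food_groups(), c("seafood", "rice", "wheat"))[1])
})

test_that("planted linear effects dominate the winner's ranking", {
  beta <- numeric(26)
  beta[c(1, 5, 9)] <- c(0.6, 0.45, 0.3)
  d <- mk_xy(800, seed = 6, beta = beta)
  cfg <- ranking_config(seed = 6)
  idx <- split_cohort(800, cfg)
  fits <- lapply(c("linear", "forest"), function(fam) {
    fit_family(d$x[idx$train, ], d$y[idx$train], fam, cfg)
  })
  res <- compare_and_rank(fits, d$x[idx$test, ], d$y[idx$test], cfg)
  expect_setequal(res$ranking[1:3], food_groups()[c(1, 5, 9)])
  expect_equal(res$ranking, names(sort(-res$contributions)))
})

test_that("importance results serialize to JSON and CSV", {
  contrib <- stats::setNames(c(60, 40, rep(0, 24)), food_groups())
  res <- structure(list(family = "forest",
                        test_r2 = c(linear = 0.1, forest = 0.2),
                        contributions = contrib,
                        ranking = names(sort(-contrib)),
                        selected_hyperparams = list(mtry = 5)),
                   class = "importance_result")
  dir <- withr::local_tempdir()
  write_importance(res, file.path(dir, "imp.json"), file.path(dir, "rank.csv"))
  j <- jsonlite::read_json(file.path(dir, "imp.json"), simplifyVector = TRUE)
  expect_equal(j$winner, "forest")
  expect_equal(j$contributions$rice, 60)
  r <- utils::read.csv(file.path(dir, "rank.csv"))
  expect_equal(r$group[1], "rice")
})
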