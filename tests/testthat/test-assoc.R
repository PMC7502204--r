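test_that("the step-up rule matches its definition and the exhaustive oracle", {
  # hand-evaluated example: reject the two smallest, cutoff 0.02
  dec <- bh_adjust(c(0.01, 0.02, 0.04, 0.20), q = 0.05)
  expect_equal(dec$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(dec$cutoff, 0.02)
  expect_equal(dec$n_rejected, 2L)

  expect_equal(bh_adjust(rep(1, 10))$n_rejected, 0L)
  expect_equal(bh_adjust(rep(1, 10))$cutoff, 0)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")

  set.seed(20)
  for (i in 1:200) {
    m <- sample(1:8, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1, 0.2), 1)
    dec <- bh_adjust(p, q)
    expect_identical(dec$reject, oracle_bh(p, q))
    # agreement with the adjusted-p formulation
    expect_identical(dec$reject, unname(p.adjust(p, "BH") <= q) & dec$n_rejected > 0)
  }
})

test_that("band fits recover planted effects with sensible inference", {
  d <- simulate_band_cohort(n = 2500, seed = 21)
  res <- fit_association(d, model_spec("M3", "cmrs", "hds_bands"))
  truth <- attr(d, "truth")$band_effects
  expect_equal(res$estimates$level, c("<=3", "4", "5", "6", "7", ">=8"))
  expect_equal(res$estimates$beta[1], 0)
  # every planted band effect inside its 95% CI would be ~77% probable
  # jointly; require the strong top-band effect to be detected and ordered
  expect_lt(res$estimates$beta[6], res$estimates$beta[2])
  expect_lt(res$estimates$ci_lo[6], truth[6])
  expect_gt(res$estimates$ci_hi[6], truth[6])
  expect_lt(res$p_trend, 1e-6)
  expect_true(res$mixed)
  expect_true(all(res$estimates$n >= 1))
})

test_that("degenerate designs are rejected with informative errors", {
  d <- simulate_band_cohort(n = 300, seed = 22)
  d$hds_band <- factor("<=3", levels = levels(d$hds_band))
  expect_error(fit_association(d, model_spec("M1", "cmrs", "hds_bands")),
               "constant")
  d2 <- simulate_band_cohort(n = 300, seed = 22)
  d2$fiber <- d2$energy   # aliased after scaling
  expect_error(fit_association(d2, model_spec("M2", "cmrs", "hds_bands")),
               "aliased")
})

test_that("estimates are equivariant under outcome rescaling", {
  d <- simulate_band_cohort(n = 800, seed = 23)
  spec <- model_spec("M1", "cmrs", "hds_bands")
  r1 <- fit_association(d, spec)
  d2 <- d
  d2$delta_cmrs <- d2$delta_cmrs * 3
  r2 <- fit_association(d2, spec)
  expect_equal(r2$estimates$beta, r1$estimates$beta * 3, tolerance = 1e-6)
  expect_equal(r2$estimates$ci_lo, r1$estimates$ci_lo * 3, tolerance = 1e-6)
})

test_that("without cluster variance the mixed fit collapses to least squares", {
  set.seed(24)
  n <- 400
  d <- simulate_band_cohort(n = n, seed = 24, icc = 0)
  # remove any between-class signal from the outcome entirely
  cls <- split(seq_len(n), d$class_id)
  for (idx in cls) d$delta_cmrs[idx] <- d$delta_cmrs[idx] -
      mean(d$delta_cmrs[idx])
  res <- fit_association(d, model_spec("M1", "cmrs", "hds_continuous"))
  ols <- lm(delta_cmrs ~ hds + scale(base_cmrs) + scale(age) + sex, data = d)
  expect_lt(abs(res$estimates$beta - coef(ols)[["hds"]]), 1e-6)
})

test_that("the fixed-effects fallback engages below two clusters", {
  d <- simulate_band_cohort(n = 400, seed = 25)
  d$class_id <- "only_one"
  expect_warning(res <- fit_association(d, model_spec("M1", "cmrs",
                                                      "hds_continuous")),
                 "fewer than 2 clusters")
  expect_false(res$mixed)
  expect_true(is.finite(res$estimates$beta))
})

test_that("pairwise comparisons are Bonferroni-scaled and capped", {
  d <- simulate_band_cohort(n = 1200, seed = 26)
  res <- fit_association(d, model_spec("M1", "cmrs", "hds_bands"))
  pw <- pairwise_bonferroni(res)
  expect_equal(nrow(pw), choose(6, 2))
  expect_equal(pw$p_adj, pmin(1, pw$p_raw * 15))
  expect_true(all(pw$p_adj >= pw$p_raw))
  # the strongest planted contrast is the reference vs the top band
  top <- pw[pw$band_a == "<=3" & pw$band_b == ">=8", ]
  expect_lt(top$diff, 0)
  expect_error(pairwise_bonferroni(
    fit_association(d, model_spec("M1", "cmrs", "hds_continuous"))),
    "band exposure")
})

test_that("planted interactions are detected and null strata slopes pool", {
  hits <- 0
  for (s in 1:8) {
    d <- simulate_band_cohort(
      n = 1500, seed = 300 + s,
      slope_by = list(modifier = "sex",
                      slopes = c(girl = -0.3, boy = 0)))
    m <- moderation(d, "sex", model = "M1")
    if (m$interaction_p < 0.05) hits <- hits + 1
    expect_equal(nrow(m$strata), 2)
  }
  expect_gte(hits, 6)

  # no planted interaction: stratified slopes pool to the overall slope
  d0 <- simulate_band_cohort(n = 3000, seed = 27, slope = -0.2)
  m0 <- moderation(d0, "sex", model = "M1")
  pooled <- fit_association(d0, model_spec("M1", "cmrs", "hds_continuous"))
  navg <- sum(m0$strata$slope * m0$strata$n) / sum(m0$strata$n)
  expect_lt(abs(navg - pooled$estimates$beta), 0.02)
})

test_that("interaction tests keep their size under the null", {
  rejections <- 0
  for (s in 1:30) {
    d <- simulate_band_cohort(n = 500, seed = 400 + s, slope = -0.2)
    m <- moderation(d, "sex", model = "M1")
    if (m$interaction_p < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections, 5)   # binomial(30, 0.05) upper tail
})

test_that("subset analyses partition the cohort and reproduce the whole", {
  d <- simulate_band_cohort(n = 1200, seed = 28)
  spec <- model_spec("M2", "cmrs", "hds_bands")
  full <- fit_association(d, spec)
  same <- sensitivity_subset(d, spec, "all")
  expect_equal(same$estimates, full$estimates)

  ctl <- sensitivity_subset(d, spec, "control")
  trt <- sensitivity_subset(d, spec, "intervention")
  expect_equal(ctl$n + trt$n, full$n)
  # the planted monotone decrease survives in the control arm
  expect_lt(ctl$estimates$beta[6], 0)
  expect_lt(ctl$p_trend, 0.05)
  d_empty <- d[d$intervention == "control", ]
  expect_error(sensitivity_subset(d_empty, spec, "intervention"), "empty")
})

test_that("outcome families are screened with the step-up rule", {
  d <- simulate_band_cohort(n = 900, seed = 29)
  d$delta_bmi <- rnorm(900)          # pure noise outcome
  d$base_bmi <- rnorm(900)
  out <- run_associations(d, c("cmrs", "bmi"), model = "M1")
  expect_equal(names(out$p_trend), c("cmrs", "bmi"))
  expect_true(out$bh$reject[["cmrs"]])
  expect_equal(nrow(out$results), 12)
  expect_true(all(out$results$fdr_significant[out$results$outcome == "cmrs"]))
})
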