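test_that("derived measures follow their formulas", {
  panel <- tibble::tibble(child_id = "a", visit = "baseline",
                          height_cm = 125, weight_kg = 30,
                          sbp = 100, dbp = 60,
                          glucose = 5.0, insulin = 10,
                          tg = 0.9, hdl = 1.5)
  d <- derive_measures(panel)
  expect_equal(d$map, 60 + 0.33 * 40)            # 73.2 mmHg
  expect_equal(d$homa_ir, (10 * 90) / 405)       # 2.2222 with 18.0 mg/dL
  expect_equal(d$bmi, 30 / 1.25^2)               # 19.2 kg/m^2
  expect_equal(d$bp_mean, 80)
  expect_equal(d$tg_hdl, 0.6)
  expect_equal(d$sbp, panel$sbp)                 # inputs untouched

  panel$height_cm <- -1
  expect_warning(d2 <- derive_measures(panel), "non-positive")
  expect_true(is.na(d2$bmi))
})

test_that("z-scores center and scale within strata of the fitting data", {
  st <- tiny_stages()
  z <- st$z_b
  strata <- lookup <- dietcmr:::lookup_stratum(st$ref, st$covs$sex,
                                               st$covs$age)
  key <- paste(st$covs$sex, strata)[match(z$child_id, st$covs$child_id)]
  for (m in c("z_wc", "z_glucose", "z_bp_mean")) {
    for (k in unique(key)) {
      v <- z[[m]][key == k]
      v <- v[!is.na(v)]
      expect_lt(abs(mean(v)), 1e-8)
      expect_lt(abs(sd(v) - 1), 1e-8)
    }
  }
  # refitting the reference on the same data is idempotent
  ref2 <- fit_reference(st$panel_b, st$covs)
  expect_equal(ref2$strata, st$ref$strata)
})

test_that("the composite score sums its five components with HDL negated", {
  st <- tiny_stages()
  ref <- st$ref
  # construct a child one SD above the stratum mean on every component
  sx <- ref$age_map$sex[1]
  ages <- ref$age_map$age[ref$age_map$sex == sx &
                            ref$age_map$stratum == ref$age_map$stratum[1]]
  stat <- function(m, f) {
    s <- ref$strata
    s[[f]][s$measure == m & s$sex == sx &
             s$stratum == ref$age_map$stratum[1]]
  }
  mk_panel <- function(shift) {
    bp <- stat("bp_mean", "mean") + shift * stat("bp_mean", "sd")
    tibble::tibble(
      child_id = "probe", visit = "baseline",
      wc = stat("wc", "mean") + shift * stat("wc", "sd"),
      sbp = bp, dbp = bp,
      glucose = stat("glucose", "mean") + shift * stat("glucose", "sd"),
      hdl = stat("hdl", "mean") + shift * stat("hdl", "sd"),
      tg = stat("tg", "mean") + shift * stat("tg", "sd"))
  }
  covs <- tibble::tibble(child_id = "probe", age = ages[1], sex = sx)
  z1 <- standardize_and_score(derive_measures(mk_panel(1)), ref, covs)
  expect_equal(z1$cmrs, 1 + 1 + 1 - 1 + 1)  # = 3
  z0 <- standardize_and_score(derive_measures(mk_panel(0)), ref, covs)
  expect_equal(z0$cmrs, 0)
})

test_that("the composite is invariant to affine unit changes", {
  st <- tiny_stages()
  panel2 <- st$panel_b
  panel2$glucose <- panel2$glucose * 18 + 5   # arbitrary affine rescale
  panel2$wc <- panel2$wc / 2.54
  ref2 <- fit_reference(panel2, st$covs)
  z2 <- standardize_and_score(panel2, ref2, st$covs)
  expect_equal(z2$cmrs, st$z_b$cmrs, tolerance = 1e-10)
})

test_that("change scores subtract baseline from follow-up per measure", {
  st <- tiny_stages()
  same <- change_scores(st$z_b, st$z_b)
  dcols <- grep("^delta_", names(same), value = TRUE)
  for (m in dcols) expect_true(all(same[[m]] == 0 | is.na(same[[m]])))

  zb <- st$z_b[1, ]
  zf <- zb
  zb$cmrs <- 1.0
  zf$cmrs <- -0.5
  expect_equal(change_scores(zb, zf)$delta_cmrs, -1.5)

  # improving HDL raises its z-change but lowers the composite change
  zf2 <- zb
  zf2$z_hdl <- zb$z_hdl + 1
  zf2$cmrs <- zb$cmrs - 1
  ch <- change_scores(zb, zf2)
  expect_equal(ch$delta_hdl, 1)
  expect_equal(ch$delta_cmrs, -1)

  # a child absent at follow-up is dropped
  ch2 <- change_scores(st$z_b, st$z_f[-1, ])
  expect_equal(nrow(ch2), nrow(st$z_f) - 1)
})

test_that("single-sex cohorts collapse strata to age only", {
  st <- tiny_stages()
  girls <- st$covs[st$covs$sex == "girl", ]
  panel <- st$panel_b[st$panel_b$child_id %in% girls$child_id, ]
  ref <- fit_reference(panel, girls, min_stratum_n = 5)
  expect_true(all(ref$age_map$sex == "girl"))
  expect_gt(nrow(ref$age_map), 0)
})

test_that("degenerate strata are reported by measure and stratum", {
  panel <- tibble::tibble(child_id = sprintf("c%02d", 1:30),
                          visit = "baseline",
                          wc = 60, glucose = rnorm(30, 4.5, 0.3))
  covs <- tibble::tibble(child_id = panel$child_id, age = 9,
                         sex = rep(c("girl", "boy"), 15))
  expect_error(fit_reference(panel, covs, measures = c("wc", "glucose"),
                             min_stratum_n = 5),
               "wc")
})

test_that("standardization errors when a stratum is not covered", {
  st <- tiny_stages()
  covs <- st$covs[1, ]
  covs$age <- 40L
  panel <- st$panel_b[st$panel_b$child_id == covs$child_id, ]
  expect_error(standardize_and_score(panel, st$ref, covs),
               "stratum absent")
})

test_that("effect sizes classify against the composite-aware thresholds", {
  expect_equal(classify_effect_size(0.5), "medium")
  expect_equal(classify_effect_size(2.5, is_cmrs = TRUE), "medium")
  expect_equal(classify_effect_size(0.19), "none")
  expect_equal(classify_effect_size(-0.85), "large")
  expect_equal(classify_effect_size(c(0.1, 0.25, 0.6, 1.2)),
               c("none", "small", "medium", "large"))
  expect_equal(classify_effect_size(c(0.9, 1.0, 2.5, 4.0), is_cmrs = TRUE),
               c("none", "small", "medium", "large"))
  expect_error(classify_effect_size(Inf), "finite")
})

test_that("references round-trip through JSON", {
  st <- tiny_stages()
  path <- withr::local_tempfile(fileext = ".json")
  write_reference(st$ref, path)
  ref2 <- read_reference(path)
  z2 <- standardize_and_score(st$panel_b, ref2, st$covs)
  expect_equal(z2$cmrs, st$z_b$cmrs, tolerance = 1e-12)
})
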