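# Synthetic longitudinal cohort generator with planted diet effects.
#
# The generator emulates the statistical structure the analysis assumes:
# zero-inflated, block-correlated lognormal food-group intakes measured by
# 3-day recalls, school/class clustering, confounders, and a one-year change
# in the composite risk score equal to a planted linear function of
# standardized usual intakes plus confounder effects, a class-level random
# intercept, and unit-SD Gaussian noise (so planted slopes read directly as
# standardized effect sizes).

#' Default generative parameters for the 26 food groups
#'
#' Per group: the marginal mean intake on the energy-adjusted scale
#' (g/100 kcal/day), the probability of being a non-consumer (point mass at
#' zero), the lognormal log-scale SD among consumers, and a correlation block
#' label. The lognormal log-mean is derived so the zero-inflated marginal
#' mean matches `mean_g100`. Values are calibrated to the scale of 24-h
#' recall data in school-age children, where many groups show SD greater
#' than mean (zero inflation plus right skew).
#'
#' @return Tibble with columns `group`, `mean_g100`, `zero_prob`, `log_sd`,
#'   `log_mean`, `block`.
#' @export
default_food_group_params <- function() {
  p <- tibble::tibble(
    group = food_groups(),
    mean_g100 = c(7.0, 5.5, 2.4, 0.8, 0.8, 1.5, 1.7, 4.0, 5.0, 0.45, 0.4,
                  6.0, 2.5, 1.0, 0.7, 0.2, 0.5, 1.9, 2.5, 8.0, 2.0, 0.6,
                  0.8, 1.9, 0.5, 0.8),
    zero_prob = c(0.02, 0.03, 0.30, 0.50, 0.55, 0.40, 0.35, 0.05, 0.05,
                  0.65, 0.70, 0.10, 0.15, 0.40, 0.70, 0.85, 0.60, 0.53,
                  0.10, 0.25, 0.60, 0.70, 0.40, 0.45, 0.55, 0.60),
    log_sd = c(0.7, 0.8, 1.1, 1.0, 1.1, 1.0, 1.0, 0.8, 0.8, 1.0, 1.0, 0.9,
               0.8, 1.0, 1.1, 1.0, 1.0, 1.1, 0.8, 0.9, 0.9, 1.0, 0.9, 1.2,
               1.0, 1.0),
    # blocks follow the observed co-consumption patterns: a rice-based
    # pattern (rice with vegetables, poultry and seafood) and a wheat-based
    # pattern (wheat with refined grains, fried foods, roots/tubers and
    # fungi/algae) are internally positively correlated but separate
    block = c("rice_pattern", "wheat_pattern", "wheat_pattern",
              "plant_other", "wheat_pattern", "plant_other", "wheat_pattern",
              "rice_pattern", "rice_pattern", "wheat_pattern", "plant_other",
              "plant_other", "meat_eggs", "rice_pattern", "meat_eggs",
              "meat_eggs", "meat_eggs", "rice_pattern", "meat_eggs",
              "dairy", "dairy", "dairy", "snacks", "snacks", "snacks",
              "snacks")
  )
  p$log_mean <- log(p$mean_g100 / (1 - p$zero_prob)) - p$log_sd^2 / 2
  p
}

#' Planted effects replicating the nine leading determinants
#'
#' Slopes of one-year change in CMRS per SD of usual intake: negative
#' (protective, high intake healthy) for seafood, rice, and red meat other
#' than pork; positive (adverse, low intake healthy) for refined grains,
#' fried foods, sugar-sweetened beverages, wheat, fungi and algae, and roots
#' and tubers. Magnitudes descend over the planted set from 0.30 to 0.05.
#'
#' @return Named numeric vector of length 26 (zero off the planted set).
#' @export
paper_like_effects <- function() {
  eff <- stats::setNames(numeric(26), food_groups())
  eff["refined_grains"] <- 0.30
  eff["seafood"] <- -0.27
  eff["fried_foods"] <- 0.23
  eff["ssb"] <- 0.20
  eff["wheat"] <- 0.17
  eff["red_meat_other_than_pork"] <- -0.14
  eff["rice"] <- -0.11
  eff["fungi_algae"] <- 0.08
  eff["roots_tubers"] <- 0.05
  eff
}

default_confounder_params <- function() {
  list(age = 0.05,        # change in CMRS per year of age
       boy = 0.10,        # boys vs girls
       intervention = -0.15,
       met_sd = -0.05,    # per SD of weekly MET
       mother_edu_high = -0.10)
}

default_followup_drift <- function() {
  c(wc = 2.5, bp = 1.0, glucose = 0.05, hdl = 0.0, tg = 0.02,
    bmi = 0.4, pbf = 0.2, insulin = 0.8, tc = 0.05, ldl = 0.05,
    height = 5.5)
}

#' Simulation configuration
#'
#' Bundles and validates all generator knobs. The same configuration (which
#' embeds the seed) always yields an identical cohort.
#'
#' @param n_children Number of children (>= 1).
#' @param seed Integer seed; all randomness flows from it.
#' @param n_schools,classes_per_school Cluster structure; intervention is
#'   assigned to half the schools.
#' @param food_group_params See [default_food_group_params()].
#' @param effect_vector Named slopes of change-in-CMRS per SD of usual
#'   intake; default all zero.
#' @param confounder_params Named list of confounder effects on the change
#'   score.
#' @param noise_sd SD of the residual change-score noise (default 1, so
#'   planted slopes are standardized effect sizes).
#' @param icc Intraclass correlation of the change score within classes.
#' @param day_cv Within-child day-to-day coefficient of variation of group
#'   intakes (recalls give no direct estimate; 0.30 is a free parameter).
#' @param block_rho Latent correlation of intakes within a block.
#' @param diet_confounding Coupling of the confounder index into diet
#'   latents; 0 (default) makes diet exogenous, positive values make the
#'   adjustment models distinguishable.
#' @param secondary_share Fraction of the planted change-score signal passed
#'   to BMI, percent body fat and insulin changes.
#' @param followup_drift Named per-outcome raw-scale drifts over one year.
#' @param followup_diet_log_sd Log-scale SD of year-to-year drift in usual
#'   intakes.
#' @param energy_mean,energy_sd Marginal mean/SD of daily energy (kcal).
#' @param missing_prob_baseline,missing_prob_followup Per-field missingness
#'   of blood measures and percent body fat.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_children = 3000, seed = 1L, n_schools = 12,
                       classes_per_school = 4,
                       food_group_params = default_food_group_params(),
                       effect_vector = NULL,
                       confounder_params = default_confounder_params(),
                       noise_sd = 1.0, icc = 0.05, day_cv = 0.30,
                       block_rho = 0.3, diet_confounding = 0,
                       secondary_share = 0.15,
                       followup_drift = default_followup_drift(),
                       followup_diet_log_sd = 0.25,
                       energy_mean = 1270, energy_sd = 530,
                       missing_prob_baseline = 0.02,
                       missing_prob_followup = 0.03) {
  abort_if(length(n_children) != 1 || is.na(n_children) || n_children < 1,
           "n_children must be a positive count")
  if (is.null(effect_vector)) {
    effect_vector <- stats::setNames(numeric(26), food_groups())
  }
  abort_if(!all(food_groups() %in% names(effect_vector)),
           "effect_vector must be named by the 26 food groups")
  effect_vector <- effect_vector[food_groups()]
  p <- food_group_params
  require_columns(p, c("group", "zero_prob", "log_mean", "log_sd", "block"),
                  "food_group_params")
  abort_if(any(p$zero_prob < 0 | p$zero_prob > 1),
           "zero_prob must lie in [0, 1]")
  abort_if(any(p$log_sd <= 0), "log_sd must be positive")
  abort_if(noise_sd < 0 || icc < 0 || icc >= 1, "invalid noise_sd or icc")
  # fail early if a block correlation matrix would not be positive definite
  for (b in unique(p$block)) {
    chol_ok <- tryCatch({
      chol(exch_cor(sum(p$block == b), block_rho)); TRUE
    }, error = function(e) FALSE)
    abort_if(!chol_ok, "correlation block '", b, "' is not positive definite")
  }
  structure(list(
    n_children = as.integer(n_children), seed = as.integer(seed),
    n_schools = n_schools, classes_per_school = classes_per_school,
    food_group_params = p, effect_vector = effect_vector,
    confounder_params = confounder_params, noise_sd = noise_sd, icc = icc,
    day_cv = day_cv, block_rho = block_rho,
    diet_confounding = diet_confounding, secondary_share = secondary_share,
    followup_drift = followup_drift,
    followup_diet_log_sd = followup_diet_log_sd,
    energy_mean = energy_mean, energy_sd = energy_sd,
    missing_prob_baseline = missing_prob_baseline,
    missing_prob_followup = missing_prob_followup
  ), class = "sim_config")
}

# energy density (kcal/g) per group, used only to apportion a day's energy
# across recorded items
group_energy_density <- function() {
  stats::setNames(
    c(1.16, 2.3, 3.0, 1.5, 4.0, 3.0, 0.9, 0.35, 0.25, 0.3, 0.4, 0.55,
      3.0, 1.9, 1.9, 1.3, 2.6, 1.1, 1.5, 0.6, 0.8, 3.5, 1.2, 0.45, 3.9, 3.2),
    food_groups())
}

gen_covariates <- function(n, config) {
  school_id <- sprintf("s%02d", sample(rep_len(seq_len(config$n_schools), n)))
  class_id <- paste0(school_id, sprintf("_k%d",
                     sample.int(config$classes_per_school, n, replace = TRUE)))
  intervention_schools <- sprintf(
    "s%02d", seq_len(ceiling(config$n_schools / 2)))
  age <- as.integer(clamp(round(stats::rnorm(n, 9.5, 1.2)), 6, 13))
  sex <- sample(c("girl", "boy"), n, replace = TRUE, prob = c(0.505, 0.495))
  tibble::tibble(
    child_id = sprintf("c%05d", seq_len(n)),
    school_id = school_id,
    class_id = class_id,
    intervention = factor(
      ifelse(school_id %in% intervention_schools, "intervention", "control"),
      levels = c("control", "intervention")),
    age = age,
    sex = factor(sex, levels = c("girl", "boy")),
    grade = as.integer(clamp(age - 5L, 2L, 5L)),
    puberty = factor(sample(c("yes", "no"), n, TRUE, c(0.92, 0.08)),
                     levels = c("no", "yes")),
    met = stats::rgamma(n, shape = 1.3, scale = 480),
    income = factor(sample(c("<750", "751-1500", "1501-2500", ">=2501",
                             "Missing"), n, TRUE,
                           c(0.11, 0.31, 0.25, 0.25, 0.08))),
    mother_bmi = factor(sample(c("<24", "24-27.9", ">=28", "Missing"), n,
                               TRUE, c(0.765, 0.16, 0.025, 0.05))),
    father_bmi = factor(sample(c("<24", "24-27.9", ">=28", "Missing"), n,
                               TRUE, c(0.52, 0.34, 0.085, 0.055))),
    mother_edu = factor(sample(c("<7y", "7-12y", ">=13y", "Missing"), n,
                               TRUE, c(0.11, 0.60, 0.22, 0.07))),
    father_edu = factor(sample(c("<7y", "7-12y", ">=13y", "Missing"), n,
                               TRUE, c(0.06, 0.62, 0.25, 0.07))),
    birthweight = factor(sample(c("<2500g", "2500-3999g", ">=4000g",
                                  "Missing"), n, TRUE,
                                c(0.035, 0.79, 0.09, 0.085))),
    breastfeeding = factor(sample(c("no", "yes", "Missing"), n, TRUE,
                                  c(0.25, 0.65, 0.10))),
    fiber = exp(stats::rnorm(n, log(0.52), 0.45))
  )
}

confounder_index <- function(cov, params) {
  params$age * (cov$age - 9.5) +
    params$boy * (cov$sex == "boy") +
    params$intervention * (cov$intervention == "intervention") +
    params$met_sd * as.numeric(scale(cov$met)) +
    params$mother_edu_high * (cov$mother_edu == ">=13y")
}

# usual intakes: n x 26 matrix of g/100 kcal with zero inflation and
# block-correlated latents
gen_usual_intakes <- function(n, config, u_std) {
  p <- config$food_group_params
  usual <- matrix(0, n, nrow(p), dimnames = list(NULL, p$group))
  for (b in unique(p$block)) {
    idx <- which(p$block == b)
    R <- exch_cor(length(idx), config$block_rho)
    zc <- rmvnorm_chol(n, R)                      # consumption latent
    za <- rmvnorm_chol(n, R)                      # amount latent
    if (config$diet_confounding != 0) {
      za <- za + config$diet_confounding * u_std
    }
    for (j in seq_along(idx)) {
      g <- idx[j]
      consumer <- stats::pnorm(zc[, j]) > p$zero_prob[g]
      usual[consumer, g] <- exp(p$log_mean[g] + p$log_sd[g] * za[consumer, j])
    }
  }
  usual
}

# expand usual intakes into 3-day item-level recall records
gen_diet_records <- function(usual, energy, visit, config, map_items) {
  n <- nrow(usual)
  nz <- which(usual > 0, arr.ind = TRUE)
  groups <- colnames(usual)[nz[, 2]]
  n_days <- 3L
  k <- nrow(nz)
  day_sig <- sqrt(log(1 + config$day_cv^2))
  child <- rep(nz[, 1], each = n_days)
  grp <- rep(groups, each = n_days)
  day <- rep.int(seq_len(n_days), k)
  # day-level energy around the child's usual energy (cv 8%)
  esig <- sqrt(log(1 + 0.08^2))
  e_day_tab <- matrix(
    energy * exp(stats::rnorm(n * n_days, -esig^2 / 2, esig)), n, n_days)
  e_day <- e_day_tab[cbind(child, day)]
  dayfac <- exp(stats::rnorm(k * n_days, -day_sig^2 / 2, day_sig))
  grams <- usual[cbind(child, rep(nz[, 2], each = n_days))] *
    e_day / 100 * dayfac
  lens <- lengths(map_items)
  offsets <- stats::setNames(c(0L, cumsum(lens))[seq_along(lens)],
                             names(map_items))
  pick <- ceiling(stats::runif(length(grp)) * lens[grp])
  item <- unlist(map_items, use.names = FALSE)[offsets[grp] + pick]
  dens <- group_energy_density()[grp]
  rec <- tibble::tibble(
    visit = visit,
    child_id = sprintf("c%05d", child),
    day = day, food_item = item, grams = grams,
    raw_energy = grams * dens, e_day = e_day
  )
  # prorate item energies so each day's total equals the day's energy
  tot <- dplyr::summarise(
    dplyr::group_by(rec, .data$child_id, .data$day),
    tot = sum(.data$raw_energy), .groups = "drop")
  rec <- dplyr::left_join(rec, tot, by = c("child_id", "day"))
  rec$energy_kcal <- rec$e_day * rec$raw_energy / rec$tot
  rec[, c("visit", "child_id", "day", "food_item", "grams", "energy_kcal")]
}

stratum_sd <- function(ref, measure, sex, age) {
  st <- ref$strata[ref$strata$measure == measure, ]
  strat <- lookup_stratum(ref, sex, age)
  st$sd[match(paste(sex, strat), paste(st$sex, st$stratum))]
}

#' Simulate a longitudinal cohort
#'
#' Generates covariates with school/class clustering, zero-inflated
#' block-correlated usual food-group intakes, 3-day recall records at
#' baseline and follow-up, and baseline/follow-up cardiometabolic panels in
#' which the one-year change in the composite risk score equals
#' `sum(effect_vector * standardized usual intake) + confounder effects +
#' class random intercept + N(0, noise_sd^2)`. The change signal is split
#' equally across the five score components (waist, blood pressure, glucose,
#' HDL-C with inverted sign, triglycerides) on the z-scale of a sex-by-age
#' reference fitted to the generated baseline, then mapped back to raw units.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort`: list with `diet_records` (both visits),
#'   `covariates`, `baseline_panel`, `followup_panel`, and `truth`
#'   (the planted `effect_vector`, implied `directions`, and `usual`
#'   baseline intake matrix).
#' @export
simulate_cohort <- function(config) {
  abort_if(!inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_children
  cov <- gen_covariates(n, config)
  conf_eff <- confounder_index(cov, config$confounder_params)
  u_std <- if (stats::sd(conf_eff) > 0) as.numeric(scale(conf_eff)) else
    numeric(n)

  usual <- gen_usual_intakes(n, config, u_std)
  usual_f <- usual * exp(matrix(
    stats::rnorm(n * 26, -config$followup_diet_log_sd^2 / 2,
                 config$followup_diet_log_sd), n, 26))

  # planted change-score signal from standardized usual intakes
  s <- scale(usual)
  s[, attr(s, "scaled:scale") == 0] <- 0
  signal <- as.numeric(s %*% config$effect_vector)
  sd_b <- config$noise_sd * sqrt(config$icc / (1 - config$icc))
  classes <- unique(cov$class_id)
  b_class <- stats::setNames(stats::rnorm(length(classes), 0, sd_b), classes)
  target <- signal + conf_eff + b_class[cov$class_id]

  # baseline panel on plausible physiological scales, with an adiposity
  # latent inducing cross-measure correlation; independent of diet so the
  # baseline score carries no diet signal
  v <- stats::rnorm(n)
  age_c <- cov$age - 9.5
  boy <- as.numeric(cov$sex == "boy")
  height <- 133 + 5.8 * age_c + 1.0 * boy + stats::rnorm(n, 0, 6)
  bmi <- pmax(12, 17.2 + 0.3 * age_c + 0.15 * boy + 1.8 * v +
                stats::rnorm(n, 0, 2.2))
  sbp <- 100.5 + 1.5 * age_c + 1.0 * boy + 2.5 * v + stats::rnorm(n, 0, 9)
  dbp <- 64 + 0.9 * age_c + 0.5 * boy + 1.5 * v +
    0.45 * (sbp - (100.5 + 1.5 * age_c + 1.0 * boy)) + stats::rnorm(n, 0, 6.5)
  baseline <- tibble::tibble(
    child_id = cov$child_id, visit = "baseline",
    height_cm = height,
    weight_kg = bmi * (height / 100)^2,
    wc = 58.5 + 2.2 * age_c + 1.2 * boy + 5.5 * v + stats::rnorm(n, 0, 5),
    sbp = sbp, dbp = dbp,
    tc = 4.1 + stats::rnorm(n, 0, 0.75),
    hdl = pmax(0.4, 1.47 - 0.06 * v + stats::rnorm(n, 0, 0.28)),
    ldl = pmax(0.5, 2.1 + stats::rnorm(n, 0, 0.55)),
    tg = exp(log(0.78) + 0.25 * v + stats::rnorm(n, 0, 0.40)),
    glucose = pmax(2.5, 4.5 + 0.04 * age_c + 0.05 * boy + 0.08 * v +
                     stats::rnorm(n, 0, 0.52)),
    insulin = pmax(0.5, exp(log(8) + 0.15 * v + stats::rnorm(n, 0, 0.45))),
    pbf = clamp(24 - 1.5 * boy + 3 * v + stats::rnorm(n, 0, 3), 3, 50)
  )

  # reference on the generated baseline gives the z-to-raw scale per stratum
  ref <- fit_reference(derive_measures(baseline), cov,
                       min_stratum_n = min(20, max(2, floor(n / 4))))
  drift <- config$followup_drift
  comp_sd <- config$noise_sd / sqrt(5)
  dz <- function() target / 5 + stats::rnorm(n, 0, comp_sd)
  sdm <- function(m) stratum_sd(ref, m, cov$sex, cov$age)

  d_bp_raw <- dz() * sdm("bp_mean") + drift[["bp"]]
  zeta <- stats::rnorm(n, 0, 1.2)
  sec <- function() config$secondary_share * target + stats::rnorm(n, 0, 0.4)
  height_f <- height + drift[["height"]] + stats::rnorm(n, 0, 0.8)
  bmi_f <- pmax(12, bmi + sec() * sdm("bmi") + drift[["bmi"]])
  followup <- tibble::tibble(
    child_id = cov$child_id, visit = "followup",
    height_cm = height_f,
    weight_kg = bmi_f * (height_f / 100)^2,
    wc = baseline$wc + dz() * sdm("wc") + drift[["wc"]],
    sbp = baseline$sbp + d_bp_raw + zeta,
    dbp = baseline$dbp + d_bp_raw - zeta,
    tc = baseline$tc + drift[["tc"]] + stats::rnorm(n, 0, 0.35) * sdm("tc"),
    hdl = pmax(0.3, baseline$hdl - dz() * sdm("hdl") + drift[["hdl"]]),
    ldl = pmax(0.5, baseline$ldl + drift[["ldl"]] +
                 stats::rnorm(n, 0, 0.35) * sdm("ldl")),
    tg = pmax(0.1, baseline$tg + dz() * sdm("tg") + drift[["tg"]]),
    glucose = pmax(2.5, baseline$glucose + dz() * sdm("glucose") +
                     drift[["glucose"]]),
    insulin = pmax(0.5, baseline$insulin + sec() * sdm("insulin") +
                     drift[["insulin"]]),
    pbf = clamp(baseline$pbf + sec() * sdm("pbf") + drift[["pbf"]], 3, 50)
  )

  blot <- function(panel, prob) {
    for (f in c("tc", "hdl", "ldl", "tg", "glucose", "insulin", "pbf")) {
      panel[[f]][stats::runif(n) < prob] <- NA_real_
    }
    panel
  }
  baseline <- blot(baseline, config$missing_prob_baseline)
  followup <- blot(followup, config$missing_prob_followup)

  map <- default_food_group_map()
  map_items <- split(map$item, map$group)
  energy <- exp(stats::rnorm(
    n, log(config$energy_mean) -
      log(1 + (config$energy_sd / config$energy_mean)^2) / 2,
    sqrt(log(1 + (config$energy_sd / config$energy_mean)^2))))
  energy_f <- energy * exp(stats::rnorm(n, 0, 0.10))
  records <- dplyr::bind_rows(
    gen_diet_records(usual, energy, "baseline", config, map_items),
    gen_diet_records(usual_f, energy_f, "followup", config, map_items))

  directions <- ifelse(config$effect_vector < 0, "healthy_high",
                       ifelse(config$effect_vector > 0, "healthy_low", "none"))
  structure(list(
    diet_records = records,
    covariates = cov,
    baseline_panel = baseline,
    followup_panel = followup,
    truth = list(effect_vector = config$effect_vector,
                 directions = stats::setNames(directions, food_groups()),
                 usual = usual),
    config = config
  ), class = "synthetic_cohort")
}

#' Named fixture cohorts
#'
#' * `"tiny"`: 50 children, for unit tests and worked examples.
#' * `"null"`: no planted diet effects.
#' * `"paper-like"`: the nine planted determinants of [paper_like_effects()]
#'   with mild diet-confounder coupling.
#'
#' @param profile One of `"tiny"`, `"null"`, `"paper-like"`.
#' @param n Override the profile's default size.
#' @param seed Seed (default 1).
#' @return A `synthetic_cohort`.
#' @export
make_fixture_cohort <- function(profile = c("tiny", "null", "paper-like"),
                                n = NULL, seed = 1L) {
  profile <- match.arg(profile)
  config <- switch(profile,
    tiny = sim_config(n_children = n %||% 50, seed = seed,
                      n_schools = 4, classes_per_school = 2,
                      effect_vector = paper_like_effects()),
    null = sim_config(n_children = n %||% 1000, seed = seed),
    `paper-like` = sim_config(n_children = n %||% 3000, seed = seed,
                              effect_vector = paper_like_effects(),
                              diet_confounding = 0.10)
  )
  simulate_cohort(config)
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `diet_records.csv`, `covariates.csv`, `panel_baseline.csv`,
#' `panel_followup.csv` and `truth.json` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$diet_records, file.path(dir, "diet_records.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$baseline_panel, file.path(dir, "panel_baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$followup_panel, file.path(dir, "panel_followup.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(effect_vector = as.list(cohort$truth$effect_vector),
         directions = as.list(cohort$truth$directions)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate analysis-ready data with planted diet-score effects
#'
#' A direct generator for the association stage: covariates with class
#' clustering, an integer diet score (0-9), a baseline composite score, and
#' a change score equal to the planted per-band effect (or a linear score
#' slope, possibly modified by a covariate) plus confounder effects, a class
#' random intercept, regression toward the baseline, and Gaussian noise.
#' Used for coverage, type-I error and moderation-power simulations where a
#' band-level effect must be planted directly.
#'
#' @param n Children.
#' @param seed Seed.
#' @param band_effects Numeric length 6: planted change in the outcome for
#'   bands `<=3, 4, 5, 6, 7, >=8` (first entry is the reference, normally 0).
#' @param slope Alternative to `band_effects`: linear effect per point of
#'   the score; used when not `NULL`.
#' @param slope_by Optional named list `list(modifier = <column>, slopes =
#'   <named vector by level>)` planting an interaction.
#' @param icc,noise_sd,n_schools,classes_per_school As in [sim_config()].
#' @return Analysis-ready tibble including `hds`, `hds_band`, `delta_hds`,
#'   `base_cmrs`, `delta_cmrs`, `bmi_baseline` and diet covariates.
#' @export
simulate_band_cohort <- function(n = 2000, seed = 1L,
                                 band_effects = c(0, -0.2, -0.4, -0.6, -0.8,
                                                  -1.0),
                                 slope = NULL, slope_by = NULL,
                                 icc = 0.05, noise_sd = 1.0,
                                 n_schools = 12, classes_per_school = 4) {
  abort_if(length(band_effects) != 6, "band_effects must have length 6")
  set.seed(seed)
  config <- list(n_schools = n_schools,
                 classes_per_school = classes_per_school)
  cov <- gen_covariates(n, config)
  conf <- confounder_index(cov, default_confounder_params())
  band_probs <- c(0.15, 0.18, 0.23, 0.25, 0.14, 0.05)
  band_idx <- sample.int(6, n, replace = TRUE, prob = band_probs)
  hds <- c(list(0:3), as.list(4:7), list(8:9))[band_idx]
  hds <- vapply(hds, function(ch) ch[sample.int(length(ch), 1L)], integer(1))
  sd_b <- noise_sd * sqrt(icc / (1 - icc))
  classes <- unique(cov$class_id)
  b_class <- stats::setNames(stats::rnorm(length(classes), 0, sd_b), classes)
  base_cmrs <- stats::rnorm(n, -0.2, 2.4)
  eff <- band_effects[band_idx]
  if (!is.null(slope)) eff <- slope * as.numeric(scale(hds))
  if (!is.null(slope_by)) {
    lev <- as.character(cov[[slope_by$modifier]])
    eff <- slope_by$slopes[lev] * as.numeric(scale(hds))
    eff[is.na(eff)] <- 0
  }
  delta <- eff + conf + b_class[cov$class_id] - 0.15 * base_cmrs +
    stats::rnorm(n, 0, noise_sd)
  out <- cov
  out$bmi_baseline <- stats::rnorm(n, 17.3, 3.2)
  out$energy <- exp(stats::rnorm(n, log(1270) - 0.08, 0.4))
  out$veg_intake <- exp(stats::rnorm(n, log(8), 0.6))
  out$fruit_intake <- exp(stats::rnorm(n, log(6), 0.7))
  out$pork_intake <- exp(stats::rnorm(n, log(2.2), 0.8))
  out$nuts_intake <- exp(stats::rnorm(n, log(1.3), 0.9))
  out$hds <- hds
  out$hds_band <- hds_bands(hds)
  out$delta_hds <- as.integer(round(stats::rnorm(n, 0, 1.5)))
  out$base_cmrs <- base_cmrs
  out$delta_cmrs <- delta
  attr(out, "truth") <- list(band_effects = band_effects, slope = slope,
                             slope_by = slope_by)
  out
}
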