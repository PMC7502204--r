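# Cardiometabolic phenotypes: derived measures, age/sex standardization,
# the CMRS composite, and change scores.

# Measures standardized to z-scores. bp_mean = (SBP + DBP)/2 is the blood
# pressure component of the composite score; tg_hdl is the TG to HDL-C ratio.
z_measures <- function() {
  c("bmi", "wc", "pbf", "sbp", "dbp", "map", "tg", "tc", "hdl", "ldl",
    "tg_hdl", "glucose", "insulin", "homa_ir")
}

ref_measures <- function() c(z_measures(), "bp_mean")

# mg/dL per mmol/L of glucose, used in the HOMA-IR formula
GLUCOSE_MGDL_PER_MMOL <- 18.0

#' Derive clinical measures from raw panel fields
#'
#' Fills in body mass index, mean arterial pressure, the TG:HDL-C ratio and
#' HOMA-IR wherever their inputs are present:
#' * `bmi = weight_kg / (height_cm / 100)^2`
#' * `map = dbp + 0.33 * (sbp - dbp)` (mmHg)
#' * `homa_ir = (insulin * glucose * 18.0) / 405`, insulin in uU/L and
#'   fasting glucose converted from mmol/L to mg/dL
#' * `bp_mean = (sbp + dbp) / 2`, the blood pressure component of the
#'   composite risk score
#'
#' Percent body fat is taken as supplied (e.g. from bioimpedance) unless a
#' prediction function is given.
#'
#' @param panel Data frame with columns `child_id`, `visit`, and any of
#'   `height_cm`, `weight_kg`, `wc`, `sbp`, `dbp`, `tc`, `hdl`, `ldl`, `tg`,
#'   `glucose`, `insulin`, `pbf`.
#' @param pbf_formula Optional function of the panel returning percent body
#'   fat, for cohorts where only impedance inputs are available. `NULL`
#'   (default) keeps the supplied `pbf` column.
#' @return The panel with `bmi`, `map`, `bp_mean`, `tg_hdl`, `homa_ir`
#'   columns added or completed. Raw input columns are never modified.
#' @export
derive_measures <- function(panel, pbf_formula = NULL) {
  panel <- tibble::as_tibble(panel)
  require_columns(panel, "child_id", "panel")

  get <- function(col) {
    if (col %in% names(panel)) panel[[col]] else rep(NA_real_, nrow(panel))
  }
  height <- get("height_cm")
  weight <- get("weight_kg")
  bad <- (!is.na(height) & height <= 0) | (!is.na(weight) & weight <= 0)
  if (any(bad)) {
    warning(sum(bad), " record(s) with non-positive height or weight; ",
            "BMI set to missing", call. = FALSE)
    height[bad] <- NA_real_
    weight[bad] <- NA_real_
  }
  panel$bmi <- weight / (height / 100)^2
  sbp <- get("sbp"); dbp <- get("dbp")
  panel$map <- dbp + 0.33 * (sbp - dbp)
  panel$bp_mean <- (sbp + dbp) / 2
  panel$tg_hdl <- get("tg") / get("hdl")
  panel$homa_ir <- (get("insulin") * get("glucose") * GLUCOSE_MGDL_PER_MMOL) /
    405
  if (!is.null(pbf_formula)) panel$pbf <- pbf_formula(panel)
  panel
}

#' Fit a sex- and age-specific standardization reference
#'
#' Computes, for every measure, the mean and standard deviation within
#' sex-by-age strata (age in completed years). Sparse strata are pooled with
#' the nearest age within the same sex until every stratum holds at least
#' `min_stratum_n` children, so that stratum SDs are estimable.
#'
#' The reference should be fitted on the baseline visit and reused for
#' follow-up standardization, so that change scores reflect change in the
#' child rather than drift in the reference.
#'
#' @param panel A panel that has been through [derive_measures()].
#' @param covariates Data frame with `child_id`, `age` (years), `sex`.
#' @param measures Character vector of measures to standardize.
#' @param min_stratum_n Minimum children per stratum before pooling stops.
#' @return A `standardization_reference`: list with the stratum table
#'   (`sex`, `stratum`, `measure`, `mean`, `sd`, `n`) and the age-to-stratum
#'   map.
#' @export
fit_reference <- function(panel, covariates, measures = ref_measures(),
                          min_stratum_n = 20) {
  panel <- tibble::as_tibble(panel)
  covariates <- tibble::as_tibble(covariates)
  require_columns(covariates, c("child_id", "age", "sex"), "covariates")
  dat <- dplyr::inner_join(panel,
                           covariates[, c("child_id", "age", "sex")],
                           by = "child_id")
  abort_if(nrow(dat) == 0, "no children shared between panel and covariates")
  abort_if(anyNA(dat$age) || anyNA(dat$sex),
           "age and sex must be non-missing for all children")
  dat$age <- as.integer(floor(dat$age))
  measures <- intersect(measures, names(dat))

  # pooling: per sex, merge the smallest under-sized age bin with its
  # nearest neighbour (by age distance, ties toward younger) until all bins
  # reach min_stratum_n or a single bin remains
  age_map <- do.call(rbind, lapply(split(dat, dat$sex), function(d) {
    tab <- table(d$age)
    bins <- lapply(as.integer(names(tab)), function(a) a)
    ns <- as.integer(tab)
    while (length(bins) > 1 && min(ns) < min_stratum_n) {
      i <- which.min(ns)
      nb <- c(if (i > 1) i - 1L, if (i < length(bins)) i + 1L)
      gap <- vapply(nb, function(j) min(abs(outer(bins[[i]], bins[[j]], "-"))),
                    numeric(1))
      j <- nb[order(gap, nb)][1]
      keep <- min(i, j); drop <- max(i, j)
      bins[[keep]] <- sort(c(bins[[keep]], bins[[drop]]))
      ns[keep] <- ns[keep] + ns[drop]
      bins <- bins[-drop]; ns <- ns[-drop]
    }
    do.call(rbind, lapply(bins, function(b) {
      data.frame(sex = d$sex[1], age = b,
                 stratum = paste0(min(b), "-", max(b)))
    }))
  }))
  rownames(age_map) <- NULL

  dat <- dplyr::left_join(dat, age_map, by = c("sex", "age"))
  long <- tidyr::pivot_longer(
    dat[, c("sex", "stratum", measures)],
    cols = dplyr::all_of(measures), names_to = "measure", values_to = "value"
  )
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$stratum, .data$measure),
    mean = mean(.data$value, na.rm = TRUE),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  zero_var <- !is.na(stats_tbl$sd) & stats_tbl$sd == 0
  no_var <- is.na(stats_tbl$sd) & stats_tbl$n > 0
  if (any(zero_var | no_var)) {
    bad <- stats_tbl[zero_var | no_var, ]
    stop("zero or inestimable variance for ",
         paste(sprintf("%s in stratum %s/%s", bad$measure, bad$sex,
                       bad$stratum), collapse = "; "),
         call. = FALSE)
  }
  structure(list(strata = stats_tbl, age_map = tibble::as_tibble(age_map),
                 measures = measures, min_stratum_n = min_stratum_n),
            class = "standardization_reference")
}

lookup_stratum <- function(ref, sex, age) {
  key <- paste(sex, as.integer(floor(age)))
  map_key <- paste(ref$age_map$sex, ref$age_map$age)
  idx <- match(key, map_key)
  abort_if(anyNA(idx),
           "stratum absent from reference for sex/age: ",
           paste(unique(key[is.na(idx)]), collapse = ", "))
  ref$age_map$stratum[idx]
}

#' Standardize a panel and compute the composite risk score
#'
#' Converts each measure to a z-score against the reference strata,
#' `z = (value - stratum mean) / stratum SD`, and computes the
#' cardiometabolic risk score
#' `cmrs = z(WC) + z(BP) + z(glucose) - z(HDL-C) + z(TG)`,
#' where the blood pressure term is, by default, the z-score of the
#' per-child mean of SBP and DBP standardized as a single variable
#' (`bp_component = "combined"`); `bp_component = "average_z"` instead
#' averages the separate SBP and DBP z-scores. The composite is missing
#' whenever any of its five components is missing.
#'
#' @param panel A panel that has been through [derive_measures()].
#' @param ref A [fit_reference()] object (fitted on baseline).
#' @param covariates Data frame with `child_id`, `age`, `sex`.
#' @param bp_component `"combined"` (default) or `"average_z"`.
#' @return Tibble with `child_id`, `visit`, one `z_<measure>` column per
#'   standardized measure, and `cmrs`.
#' @export
standardize_and_score <- function(panel, ref, covariates,
                                  bp_component = c("combined", "average_z")) {
  bp_component <- match.arg(bp_component)
  panel <- tibble::as_tibble(panel)
  dat <- dplyr::inner_join(panel, covariates[, c("child_id", "age", "sex")],
                           by = "child_id")
  dat$stratum <- lookup_stratum(ref, dat$sex, dat$age)

  out <- dat[, intersect(c("child_id", "visit"), names(dat))]
  for (m in ref$measures) {
    if (!m %in% names(dat)) next
    st <- ref$strata[ref$strata$measure == m, ]
    idx <- match(paste(dat$sex, dat$stratum), paste(st$sex, st$stratum))
    out[[paste0("z_", m)]] <- (dat[[m]] - st$mean[idx]) / st$sd[idx]
  }
  z_bp <- if (bp_component == "combined") out$z_bp_mean else
    (out$z_sbp + out$z_dbp) / 2
  out$cmrs <- out$z_wc + z_bp + out$z_glucose - out$z_hdl + out$z_tg
  out
}

#' Change scores between visits
#'
#' Follow-up minus baseline for every z-score column and the composite.
#' A child missing either visit for a measure gets a missing change for
#' that measure.
#'
#' @param z_baseline,z_followup Outputs of [standardize_and_score()].
#' @return Tibble with `child_id` and `delta_*` columns.
#' @export
change_scores <- function(z_baseline, z_followup) {
  cols <- intersect(grep("^(z_|cmrs)", names(z_baseline), value = TRUE),
                    grep("^(z_|cmrs)", names(z_followup), value = TRUE))
  merged <- dplyr::inner_join(z_baseline[, c("child_id", cols)],
                              z_followup[, c("child_id", cols)],
                              by = "child_id", suffix = c("_b", "_f"))
  out <- merged["child_id"]
  for (m in cols) {
    out[[paste0("delta_", sub("^z_", "", m))]] <-
      merged[[paste0(m, "_f")]] - merged[[paste0(m, "_b")]]
  }
  out
}

#' Classify a standardized mean difference
#'
#' Effect-size bands for changes expressed as standardized mean differences:
#' 0.2 / 0.5 / 0.8 for individual cardiometabolic factors. Because the
#' composite score sums five z-scores, its bands are scaled to
#' 1.0 / 2.5 / 4.0.
#'
#' @param delta_sd Standardized mean difference (sign ignored).
#' @param is_cmrs Is the quantity the composite score?
#' @return One of `"none"`, `"small"`, `"medium"`, `"large"` (vectorized).
#' @export
classify_effect_size <- function(delta_sd, is_cmrs = FALSE) {
  abort_if(any(!is.finite(delta_sd)), "delta_sd must be finite")
  cuts <- if (isTRUE(is_cmrs)) c(1.0, 2.5, 4.0) else c(0.2, 0.5, 0.8)
  x <- abs(delta_sd)
  c("none", "small", "medium", "large")[
    1L + (x >= cuts[1]) + (x >= cuts[2]) + (x >= cuts[3])]
}

#' Serialize a standardization reference to JSON
#' @param ref A `standardization_reference`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(
    list(strata = ref$strata, age_map = ref$age_map, measures = ref$measures,
         min_stratum_n = ref$min_stratum_n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a standardization reference from JSON
#' @param path Path written by [write_reference()].
#' @return A `standardization_reference`.
#' @export
read_reference <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(strata = tibble::as_tibble(raw$strata),
                 age_map = tibble::as_tibble(raw$age_map),
                 measures = raw$measures,
                 min_stratum_n = raw$min_stratum_n),
            class = "standardization_reference")
}
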