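# Healthy Diet Score: direction assignment, definition building,
# unweighted and importance-weighted scoring.

#' Assign healthy directions to selected food groups
#'
#' Dichotomizes each selected group at its cohort median intake (groups whose
#' median is zero split as 0 vs > 0) and compares the adjusted mean change in
#' the composite risk score between the low- and high-intake strata using a
#' mixed model with a class random intercept. A group is `healthy_high` when
#' the high-intake stratum shows the lower (more favorable) adjusted change,
#' otherwise `healthy_low`.
#'
#' @param data Analysis table with one row per child: the selected groups'
#'   baseline intakes (g/100 kcal), `delta_cmrs`, `base_cmrs`, `age`, `sex`,
#'   `class_id`, plus any covariates the chosen adjustment model needs.
#' @param groups Character vector of selected group names.
#' @param model Adjustment set: `"M1"` (age, sex, baseline score; default),
#'   `"M2"` or `"M3"` (see [model_covariates()]).
#' @return Tibble with `group`, `median`, `adj_diff` (high minus low adjusted
#'   change), and `direction`.
#' @export
assign_directions <- function(data, groups, model = "M1") {
  data <- tibble::as_tibble(data)
  require_columns(data, c(groups, "delta_cmrs", "base_cmrs", "class_id"),
                  "analysis data")
  covs <- setdiff(model_covariates(model, "cmrs"), "base_cmrs")
  rows <- lapply(groups, function(g) {
    x <- data[[g]]
    med <- stats::median(x, na.rm = TRUE)
    abort_if(all(x == 0, na.rm = TRUE),
             "group '", g, "' has no consumers; cannot dichotomize")
    df <- data
    df$high_intake <- factor(ifelse(x > med, "high", "low"),
                             levels = c("low", "high"))
    fit <- fit_mixed(df, outcome = "delta_cmrs", exposure = "high_intake",
                     covariates = c("base_cmrs", covs))
    diff <- fit$coef[["high_intakehigh"]]
    tibble::tibble(group = g, median = med, adj_diff = diff,
                   direction = ifelse(diff < 0, "healthy_high", "healthy_low"))
  })
  dplyr::bind_rows(rows)
}

#' Build a Healthy Diet Score definition
#'
#' Freezes, from baseline profiles, each selected group's median cutpoint
#' (unweighted scoring) and 80th-percentile anchor (weighted prorating), the
#' healthy direction, and a weight proportional to the group's importance
#' contribution. Weights are renormalized to sum to 1 so the weighted score
#' lives on [0, 1]; `raw_percent_weights = TRUE` keeps the raw contribution
#' percentages instead (same ordering, different scale).
#'
#' @param profiles Baseline profiles from [aggregate_recalls()].
#' @param directions Output of [assign_directions()] (or a tibble with
#'   `group` and `direction`).
#' @param contributions Named contribution percentages (from an
#'   `importance_result`); must cover the selected groups.
#' @param raw_percent_weights Keep raw percentage weights (default `FALSE`).
#' @param provenance Free-text label recorded in the definition.
#' @return An `hds_definition`.
#' @export
build_definition <- function(profiles, directions, contributions,
                             raw_percent_weights = FALSE,
                             provenance = "baseline cohort") {
  groups <- directions$group
  require_columns(profiles, groups, "profiles")
  abort_if(!all(groups %in% names(contributions)),
           "contributions missing for: ",
           paste(setdiff(groups, names(contributions)), collapse = ", "))
  med <- vapply(groups, function(g) {
    stats::median(profiles[[g]], na.rm = TRUE)
  }, numeric(1))
  p80 <- vapply(groups, function(g) {
    as.numeric(stats::quantile(profiles[[g]], 0.8, na.rm = TRUE))
  }, numeric(1))
  abort_if(any(!is.finite(p80)), "non-finite 80th percentile")
  abort_if(any(p80 <= 0),
           "degenerate 80th percentile (0) for: ",
           paste(groups[p80 <= 0], collapse = ", "))
  w <- as.numeric(contributions[groups])
  if (!raw_percent_weights) w <- w / sum(w)
  structure(list(
    table = tibble::tibble(group = groups, direction = directions$direction,
                           median_cutpoint = med, anchor_zero = 0,
                           anchor_p80 = p80, weight = w),
    raw_percent_weights = raw_percent_weights,
    provenance = list(label = provenance,
                      date = format(Sys.Date()))),
    class = "hds_definition")
}

#' Unweighted Healthy Diet Score
#'
#' One point per selected group on the favorable side of its median: strictly
#' above the median for `healthy_high` groups, at or below the median for
#' `healthy_low` groups (so a child sitting exactly at every median scores a
#' point for each `healthy_low` group and none for the `healthy_high` ones).
#' For groups whose median is zero the rule reduces to any-consumption vs
#' none.
#'
#' @param profiles Profile table carrying the definition's group columns
#'   (g/100 kcal).
#' @param defn An `hds_definition`.
#' @return Integer vector in `0..k`.
#' @export
score_unweighted <- function(profiles, defn) {
  tab <- defn$table
  pts <- vapply(seq_len(nrow(tab)), function(i) {
    x <- profiles[[tab$group[i]]]
    if (tab$direction[i] == "healthy_high") as.integer(x > tab$median_cutpoint[i])
    else as.integer(x <= tab$median_cutpoint[i])
  }, integer(nrow(profiles)))
  if (nrow(profiles) == 1) pts <- matrix(pts, nrow = 1)
  as.integer(rowSums(pts))
}

#' Weighted Healthy Diet Score
#'
#' Linearly prorated sub-scores weighted by importance: for a `healthy_high`
#' group the sub-score rises from 0 at zero intake to 1 at or above the
#' baseline 80th percentile; for a `healthy_low` group it falls from 1 at
#' zero intake to 0 at or above the 80th percentile. The score is the
#' weight-sum of sub-scores (in [0, 1] under normalized weights).
#'
#' @inheritParams score_unweighted
#' @return Numeric vector.
#' @export
score_weighted <- function(profiles, defn) {
  tab <- defn$table
  abort_if(any(tab$anchor_p80 <= 0), "definition has a zero prorating anchor")
  sub <- vapply(seq_len(nrow(tab)), function(i) {
    frac <- clamp(profiles[[tab$group[i]]] / tab$anchor_p80[i], 0, 1)
    if (tab$direction[i] == "healthy_high") frac else 1 - frac
  }, numeric(nrow(profiles)))
  if (nrow(profiles) == 1) sub <- matrix(sub, nrow = 1)
  as.numeric(sub %*% tab$weight)
}

#' Score a cohort at both visits with a frozen definition
#'
#' Both visits are scored against the baseline-derived cutpoints and anchors
#' (the definition is frozen so that a change in score reflects a change in
#' diet). The change is follow-up minus baseline; children absent at a visit
#' get missing scores there.
#'
#' @param baseline_profiles,followup_profiles Profile tables (one row per
#'   child) carrying the definition's groups.
#' @param defn An `hds_definition`.
#' @return Tibble with `child_id`, `hds_baseline`, `hds_followup`,
#'   `delta_hds`, `whds_baseline`, `whds_followup`, `delta_whds`.
#' @export
score_cohort <- function(baseline_profiles, followup_profiles, defn) {
  b <- tibble::tibble(child_id = baseline_profiles$child_id,
                      hds_baseline = score_unweighted(baseline_profiles, defn),
                      whds_baseline = score_weighted(baseline_profiles, defn))
  f <- tibble::tibble(child_id = followup_profiles$child_id,
                      hds_followup = score_unweighted(followup_profiles, defn),
                      whds_followup = score_weighted(followup_profiles, defn))
  out <- dplyr::full_join(b, f, by = "child_id")
  out$delta_hds <- out$hds_followup - out$hds_baseline
  out$delta_whds <- out$whds_followup - out$whds_baseline
  out
}

#' Band an unweighted score for tabular analysis
#'
#' The six analysis bands: `<=3`, `4`, `5`, `6`, `7`, `>=8` (lowest is the
#' reference level).
#'
#' @param hds Integer scores in 0..9.
#' @return Ordered-level factor.
#' @export
hds_bands <- function(hds) {
  cut(hds, breaks = c(-Inf, 3, 4, 5, 6, 7, Inf),
      labels = c("<=3", "4", "5", "6", "7", ">=8"))
}

#' Serialize an HDS definition to JSON
#'
#' A serialized definition can be applied unchanged to an external cohort.
#'
#' @param defn An `hds_definition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hds_definition <- function(defn, path) {
  jsonlite::write_json(list(table = defn$table,
                            raw_percent_weights = defn$raw_percent_weights,
                            provenance = defn$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an HDS definition from JSON
#' @param path Path written by [write_hds_definition()].
#' @return An `hds_definition`.
#' @export
read_hds_definition <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = tibble::as_tibble(raw$table),
                 raw_percent_weights = isTRUE(raw$raw_percent_weights),
                 provenance = raw$provenance),
            class = "hds_definition")
}
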