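# 24-hour recall aggregation and energy adjustment.

#' Aggregate recall records into energy-adjusted food-group profiles
#'
#' Sums grams within child, day and food group, averages over the child's
#' recall days (a group not eaten on a day contributes 0 g for that day),
#' averages daily energy the same way, and expresses each group as grams per
#' 100 kcal of total energy: `100 * grams_per_day / energy_kcal_per_day`.
#'
#' @param records Recall records: data frame with columns `child_id`, `day`,
#'   `food_item`, `grams`, `energy_kcal` (and optionally `visit`; if present,
#'   aggregation is done within visit).
#' @param map A `food_group_map` (default [default_food_group_map()]).
#' @return Tibble with one row per child (and visit), columns
#'   `energy_kcal_day`, the 26 group intakes in g/100 kcal named by group,
#'   and companion `<group>_gday` columns in g/day. Children whose recorded
#'   energy is zero are dropped with a message and listed in the
#'   `"excluded_zero_energy"` attribute.
#' @export
aggregate_recalls <- function(records, map = default_food_group_map()) {
  records <- tibble::as_tibble(records)
  require_columns(records, c("child_id", "day", "food_item", "grams",
                             "energy_kcal"), "diet records")
  map <- as_food_group_map(map)
  unmapped <- setdiff(unique(records$food_item), map$item)
  abort_if(length(unmapped) > 0,
           "unmapped food item(s): ", paste(unmapped, collapse = ", "))
  has_visit <- "visit" %in% names(records)
  if (!has_visit) records$visit <- "baseline"
  records$group <- map$group[match(records$food_item, map$item)]

  day_tot <- dplyr::summarise(
    dplyr::group_by(records, .data$visit, .data$child_id, .data$day),
    energy = sum(.data$energy_kcal), .groups = "drop")
  energy <- dplyr::summarise(
    dplyr::group_by(day_tot, .data$visit, .data$child_id),
    energy_kcal_day = mean(.data$energy), n_days = dplyr::n(),
    .groups = "drop")

  # per-group g/day: total grams over all days / number of recall days
  grp <- dplyr::summarise(
    dplyr::group_by(records, .data$visit, .data$child_id, .data$group),
    grams = sum(.data$grams), .groups = "drop")
  grp <- dplyr::left_join(grp, energy, by = c("visit", "child_id"))
  grp$g_day <- grp$grams / grp$n_days
  wide <- tidyr::pivot_wider(
    grp[, c("visit", "child_id", "group", "g_day")],
    names_from = "group", values_from = "g_day", values_fill = 0)
  for (g in setdiff(food_groups(), names(wide))) wide[[g]] <- 0

  prof <- dplyr::left_join(energy, wide, by = c("visit", "child_id"))
  zero_energy <- prof$child_id[prof$energy_kcal_day <= 0]
  if (length(zero_energy) > 0) {
    message(length(zero_energy),
            " child(ren) with zero recorded energy excluded")
    prof <- prof[prof$energy_kcal_day > 0, ]
  }
  out <- prof[, c(if (has_visit) "visit", "child_id", "energy_kcal_day")]
  for (g in food_groups()) {
    out[[g]] <- 100 * prof[[g]] / prof$energy_kcal_day
    out[[paste0(g, "_gday")]] <- prof[[g]]
  }
  attr(out, "excluded_zero_energy") <- zero_energy
  out
}

#' Extract the 26-column intake matrix from a profile table
#'
#' @param profiles Output of [aggregate_recalls()].
#' @param scale `"g100"` for g/100 kcal (default) or `"gday"` for g/day.
#' @return Numeric matrix, one row per profile row, columns in
#'   [food_groups()] order.
#' @export
profile_matrix <- function(profiles, scale = c("g100", "gday")) {
  scale <- match.arg(scale)
  cols <- if (scale == "g100") food_groups() else paste0(food_groups(), "_gday")
  m <- as.matrix(profiles[, cols])
  colnames(m) <- food_groups()
  rownames(m) <- profiles$child_id
  m
}

#' Apply the cohort exclusion filters
#'
#' Removes children whose mean daily energy intake lies outside the
#' plausibility bounds (strictly below `min_energy` or strictly above
#' `max_energy` kcal/day), children present in the baseline panel without a
#' dietary assessment, and children missing every cardiometabolic
#' measurement at baseline.
#'
#' @param profiles Baseline profiles from [aggregate_recalls()].
#' @param baseline_panel Baseline panel (used for the no-diet and all-missing
#'   checks); `NULL` skips the panel-based exclusions.
#' @param min_energy,max_energy Energy bounds in kcal/day (defaults 300 and
#'   3500).
#' @return List with `profiles` (retained rows) and `log`, a tibble of
#'   exclusion counts per reason.
#' @export
apply_exclusions <- function(profiles, baseline_panel = NULL,
                             min_energy = 300, max_energy = 3500) {
  profiles <- tibble::as_tibble(profiles)
  low <- profiles$energy_kcal_day < min_energy
  high <- profiles$energy_kcal_day > max_energy

  all_missing_ids <- character(0)
  no_diet <- 0L
  if (!is.null(baseline_panel)) {
    panel <- tibble::as_tibble(baseline_panel)
    meas <- intersect(c("height_cm", "weight_kg", "wc", "sbp", "dbp", "tc",
                        "hdl", "ldl", "tg", "glucose", "insulin", "pbf",
                        "bmi", "map", "homa_ir"), names(panel))
    all_na <- rowSums(!is.na(panel[, meas])) == 0
    all_missing_ids <- panel$child_id[all_na]
    no_diet <- sum(!panel$child_id %in% profiles$child_id)
  }
  panel_excl <- profiles$child_id %in% all_missing_ids
  drop <- low | high | panel_excl
  log <- tibble::tibble(
    reason = c("no_dietary_assessment", "energy_below_minimum",
               "energy_above_maximum", "all_cardiometabolic_missing",
               "retained"),
    n = c(no_diet, sum(low), sum(high & !low), sum(panel_excl & !low & !high),
          sum(!drop)))
  if (sum(!drop) == 0) warning("all children excluded", call. = FALSE)
  list(profiles = profiles[!drop, ], log = log)
}
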