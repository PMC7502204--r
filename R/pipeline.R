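# End-to-end orchestration: simulate -> diet -> phenotypes -> ranking ->
# score construction -> associations, with reproducible seeding and
# delimited artifacts.

#' Assemble the analysis-ready table
#'
#' Joins covariates, baseline diet covariates (energy and the vegetable,
#' fruit, pork and nuts/legumes intakes used by the M2/M3 adjustment sets),
#' raw baseline BMI, the baseline z-scores (`base_<measure>`), and the
#' change scores (`delta_<measure>`), keeping only children retained in the
#' profile table.
#'
#' @param covariates Covariate table.
#' @param profiles_baseline Retained baseline profiles.
#' @param z_baseline Baseline output of [standardize_and_score()].
#' @param changes Output of [change_scores()].
#' @param baseline_panel Baseline panel after [derive_measures()] (for raw
#'   BMI).
#' @return Analysis-ready tibble, one row per retained child.
#' @export
prepare_analysis_data <- function(covariates, profiles_baseline, z_baseline,
                                  changes, baseline_panel) {
  diet_cov <- tibble::tibble(
    child_id = profiles_baseline$child_id,
    energy = profiles_baseline$energy_kcal_day,
    veg_intake = profiles_baseline$deep_color_vegetables +
      profiles_baseline$light_color_vegetables,
    fruit_intake = profiles_baseline$fruits,
    pork_intake = profiles_baseline$pork,
    nuts_intake = profiles_baseline$nuts_legumes)
  base <- z_baseline
  names(base) <- sub("^z_", "base_", names(base))
  names(base)[names(base) == "cmrs"] <- "base_cmrs"
  bmi <- tibble::tibble(child_id = baseline_panel$child_id,
                        bmi_baseline = baseline_panel$bmi)
  out <- dplyr::inner_join(covariates, diet_cov, by = "child_id")
  out <- dplyr::left_join(out, bmi, by = "child_id")
  out <- dplyr::left_join(out, base[, c("child_id",
                                        grep("^base_", names(base),
                                             value = TRUE))],
                          by = "child_id")
  out <- dplyr::left_join(out, changes, by = "child_id")
  # the selected groups' baseline intakes, for direction assignment
  dplyr::left_join(out, profiles_baseline[, c("child_id", food_groups())],
                   by = "child_id")
}

#' Pipeline configuration
#'
#' One master seed deterministically derives the stage seeds.
#'
#' @param seed Master seed.
#' @param sim A [sim_config()] (its seed is overridden by the derived stage
#'   seed).
#' @param ranking A [ranking_config()] (idem).
#' @param k Number of leading determinants for the score (default 9).
#' @param direction_model Adjustment set for direction assignment
#'   (default `"M1"`).
#' @param assoc_model Adjustment set for the association stage (default
#'   `"M3"`).
#' @param outcomes Outcome measures for the association family (default:
#'   the composite score plus the 14 standardized factors).
#' @param fdr_q FDR level (default 0.05).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(),
                            ranking = ranking_config(), k = 9,
                            direction_model = "M1", assoc_model = "M3",
                            outcomes = c("cmrs", z_measures()),
                            fdr_q = 0.05) {
  sim$seed <- derive_seed(seed, 11L)
  ranking$seed <- derive_seed(seed, 12L)
  structure(list(seed = as.integer(seed), sim = sim, ranking = ranking,
                 k = k, direction_model = direction_model,
                 assoc_model = assoc_model, outcomes = outcomes,
                 fdr_q = fdr_q),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes simulate, diet aggregation and exclusions, phenotype
#' standardization and change scores, determinant ranking, diet-score
#' construction and scoring, and the association stage. With `out_dir`,
#' writes all stage artifacts (CSV/JSON) plus a manifest of seeds and file
#' checksums; reruns with the same configuration are identical for every
#' deterministic stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List with all stage objects, invisibly when writing.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cohort <- stage("simulate", simulate_cohort(config$sim))

  profiles <- stage("diet", aggregate_recalls(cohort$diet_records))
  prof_b <- profiles[profiles$visit == "baseline", ]
  prof_f <- profiles[profiles$visit == "followup", ]
  excl <- stage("diet", apply_exclusions(prof_b, cohort$baseline_panel))
  prof_b <- excl$profiles
  prof_f <- prof_f[prof_f$child_id %in% prof_b$child_id, ]

  covs <- cohort$covariates[cohort$covariates$child_id %in% prof_b$child_id, ]
  panel_b <- stage("phenotypes", derive_measures(
    cohort$baseline_panel[cohort$baseline_panel$child_id %in%
                            prof_b$child_id, ]))
  panel_f <- stage("phenotypes", derive_measures(
    cohort$followup_panel[cohort$followup_panel$child_id %in%
                            prof_b$child_id, ]))
  ref <- stage("phenotypes", fit_reference(panel_b, covs))
  z_b <- stage("phenotypes", standardize_and_score(panel_b, ref, covs))
  z_f <- stage("phenotypes", standardize_and_score(panel_f, ref, covs))
  changes <- stage("phenotypes", change_scores(z_b, z_f))

  data <- stage("phenotypes", prepare_analysis_data(
    covs, prof_b, z_b, changes, panel_b))

  keep <- !is.na(data$delta_cmrs)
  importance <- stage("ranking", rank_determinants(
    profile_matrix(prof_b)[keep, , drop = FALSE],
    data$delta_cmrs[keep], config$ranking))
  leading <- select_leading(importance, config$k)

  directions <- stage("hds", assign_directions(
    data, leading, model = config$direction_model))
  defn <- stage("hds", build_definition(
    prof_b, directions, importance$contributions,
    provenance = paste0("synthetic cohort seed ", config$seed)))
  scores <- stage("hds", score_cohort(prof_b, prof_f, defn))
  data <- dplyr::left_join(data, scores, by = "child_id")
  data$hds <- data$hds_baseline
  data$hds_band <- hds_bands(data$hds)

  assoc <- stage("assoc", run_associations(
    data, config$outcomes, model = config$assoc_model,
    exposure = "hds_bands", fdr_q = config$fdr_q))

  result <- list(config = config, cohort = cohort, profiles = profiles,
                 exclusions = excl$log, reference = ref, changes = changes,
                 importance = importance, leading = leading,
                 directions = directions, definition = defn,
                 scores = scores, data = data, assoc = assoc)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    utils::write.csv(prof_b, file.path(out_dir, "profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(excl$log, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    write_reference(ref, file.path(out_dir, "reference.json"))
    utils::write.csv(changes, file.path(out_dir, "changes.csv"),
                     row.names = FALSE)
    write_importance(importance, file.path(out_dir, "importance.json"),
                     file.path(out_dir, "ranking.csv"))
    write_hds_definition(defn, file.path(out_dir, "hds_definition.json"))
    utils::write.csv(scores, file.path(out_dir, "hds.csv"), row.names = FALSE)
    utils::write.csv(assoc$results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("dietcmr")),
      seed = config$seed,
      stage_seeds = list(sim = config$sim$seed,
                         ranking = config$ranking$seed),
      checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(result))
  }
  result
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys: `seed`, `k`, `direction_model`, `assoc_model`,
#' `fdr_q`, `outcomes`, and nested `sim` / `ranking` blocks whose entries
#' override the corresponding [sim_config()] and [ranking_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  if (!is.null(sim_args$effect_vector)) {
    ev <- stats::setNames(numeric(26), food_groups())
    ev[names(sim_args$effect_vector)] <- unlist(sim_args$effect_vector)
    sim_args$effect_vector <- ev
  }
  rank_args <- raw$ranking %||% list()
  args <- list(seed = raw$seed %||% 1L,
               sim = do.call(sim_config, sim_args),
               ranking = do.call(ranking_config, rank_args))
  for (key in c("k", "direction_model", "assoc_model", "fdr_q", "outcomes")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(pipeline_config, args)
}
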