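# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_cohort <- function() memo("tiny", make_fixture_cohort("tiny"))

# tiny cohort pushed through diet + phenotype stages
tiny_stages <- function() memo("tiny_stages", {
  co <- tiny_cohort()
  prof <- aggregate_recalls(co$diet_records)
  pb <- apply_exclusions(prof[prof$visit == "baseline", ],
                         co$baseline_panel)$profiles
  pf <- prof[prof$visit == "followup" & prof$child_id %in% pb$child_id, ]
  covs <- co$covariates[co$covariates$child_id %in% pb$child_id, ]
  panel_b <- derive_measures(
    co$baseline_panel[co$baseline_panel$child_id %in% pb$child_id, ])
  panel_f <- derive_measures(
    co$followup_panel[co$followup_panel$child_id %in% pb$child_id, ])
  ref <- fit_reference(panel_b, covs)
  z_b <- standardize_and_score(panel_b, ref, covs)
  z_f <- standardize_and_score(panel_f, ref, covs)
  changes <- change_scores(z_b, z_f)
  data <- prepare_analysis_data(covs, pb, z_b, changes, panel_b)
  list(cohort = co, prof_b = pb, prof_f = pf, covs = covs,
       panel_b = panel_b, panel_f = panel_f, ref = ref, z_b = z_b,
       z_f = z_f, changes = changes, data = data)
})

# run diet + phenotype stages on any cohort (returns analysis pieces)
cohort_stages <- function(co) {
  prof <- aggregate_recalls(co$diet_records)
  pb <- apply_exclusions(prof[prof$visit == "baseline", ],
                         co$baseline_panel)$profiles
  covs <- co$covariates[co$covariates$child_id %in% pb$child_id, ]
  panel_b <- derive_measures(
    co$baseline_panel[co$baseline_panel$child_id %in% pb$child_id, ])
  panel_f <- derive_measures(
    co$followup_panel[co$followup_panel$child_id %in% pb$child_id, ])
  ref <- fit_reference(panel_b, covs)
  z_b <- standardize_and_score(panel_b, ref, covs)
  z_f <- standardize_and_score(panel_f, ref, covs)
  changes <- change_scores(z_b, z_f)
  data <- prepare_analysis_data(covs, pb, z_b, changes, panel_b)
  list(prof_b = pb, covs = covs, ref = ref, z_b = z_b, changes = changes,
       data = data)
}

# a small hand-made score definition: 3 healthy_high + 6 healthy_low groups
toy_definition <- function(median = 1, p80 = 2) {
  groups <- c("seafood", "rice", "red_meat_other_than_pork",
              "refined_grains", "fried_foods", "ssb", "wheat", "fungi_algae",
              "roots_tubers")
  structure(list(
    table = tibble::tibble(
      group = groups,
      direction = c(rep("healthy_high", 3), rep("healthy_low", 6)),
      median_cutpoint = median, anchor_zero = 0, anchor_p80 = p80,
      weight = rep(1 / 9, 9)),
    raw_percent_weights = FALSE,
    provenance = list(label = "toy", date = "2026-01-01")),
    class = "hds_definition")
}

toy_profiles <- function(values, groups = toy_definition()$table$group) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  colnames(values) <- groups
  df <- tibble::as_tibble(as.data.frame(values))
  df$child_id <- sprintf("c%03d", seq_len(nrow(df)))
  df
}
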