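test_that("directions follow the adjusted low/high comparison", {
  set.seed(10)
  n <- 600
  d <- tibble::tibble(
    child_id = sprintf("c%03d", 1:n),
    class_id = sample(sprintf("k%02d", 1:20), n, TRUE),
    age = sample(7:12, n, TRUE),
    sex = factor(sample(c("girl", "boy"), n, TRUE)),
    base_cmrs = rnorm(n, 0, 2),
    fried_foods = rexp(n, 1),            # harmful: high intake worsens
    seafood = rexp(n, 1))                # protective: high intake improves
  noise <- rnorm(n, 0, 0.6)
  d$delta_cmrs <- 0.8 * (d$fried_foods > median(d$fried_foods)) -
    0.8 * (d$seafood > median(d$seafood)) - 0.1 * d$base_cmrs + noise
  dir <- assign_directions(d, c("fried_foods", "seafood"))
  expect_equal(dir$direction[dir$group == "fried_foods"], "healthy_low")
  expect_equal(dir$direction[dir$group == "seafood"], "healthy_high")
  expect_gt(dir$adj_diff[dir$group == "fried_foods"], 0)

  d$rice <- 0
  expect_error(assign_directions(d, "rice"), "no consumers")
})

test_that("definitions freeze baseline cutpoints, anchors and weights", {
  st <- tiny_stages()
  groups <- toy_definition()$table$group
  directions <- tibble::tibble(group = groups,
                               direction = toy_definition()$table$direction)
  contrib <- stats::setNames(c(19.6, 15, 12, 10, 9, 8, 7, 5, 3.9), groups)
  defn <- build_definition(st$prof_b, directions, contrib)
  expect_s3_class(defn, "hds_definition")
  expect_equal(sum(defn$table$weight), 1)
  expect_equal(defn$table$weight,
               as.numeric(contrib[defn$table$group] / sum(contrib)))
  expect_true(all(defn$table$anchor_p80 > 0))
  expect_true(all(defn$table$anchor_zero == 0))

  # deterministic: same cohort in, same definition out
  defn2 <- build_definition(st$prof_b, directions, contrib)
  expect_equal(defn$table, defn2$table)

  # raw-percent variant only rescales the weights
  defn_raw <- build_definition(st$prof_b, directions, contrib,
                               raw_percent_weights = TRUE)
  expect_equal(defn_raw$table$weight / sum(defn_raw$table$weight),
               defn$table$weight)

  # serialized definitions score identically after reload
  path <- withr::local_tempfile(fileext = ".json")
  write_hds_definition(defn, path)
  defn3 <- read_hds_definition(path)
  expect_equal(score_unweighted(st$prof_b, defn3),
               score_unweighted(st$prof_b, defn))
  expect_equal(score_weighted(st$prof_b, defn3),
               score_weighted(st$prof_b, defn), tolerance = 1e-12)
})

test_that("unweighted scoring applies the median rule with its boundary", {
  defn <- toy_definition(median = 1, p80 = 2)
  hh <- defn$table$group[defn$table$direction == "healthy_high"]
  hl <- defn$table$group[defn$table$direction == "healthy_low"]

  best <- toy_profiles(rep(0, 9))
  best[hh] <- 2                                  # above median on protective
  expect_equal(score_unweighted(best, defn), 9L)

  boundary <- toy_profiles(rep(1, 9))            # exactly at every median
  expect_equal(score_unweighted(boundary, defn), 6L)  # the 6 healthy_low

  worst <- toy_profiles(rep(2, 9))
  worst[hh] <- 0
  expect_equal(score_unweighted(worst, defn), 0L)
})

test_that("weighted scoring prorates linearly between the anchors", {
  defn <- toy_definition(median = 1, p80 = 2)
  hh <- defn$table$group[defn$table$direction == "healthy_high"]
  hl <- defn$table$group[defn$table$direction == "healthy_low"]

  # zero intake of a harmful group earns that group's full sub-score
  p <- toy_profiles(rep(2, 9))
  p[hh] <- 0                 # no protective intake: those sub-scores are 0
  p[hl[1]] <- 0
  w <- score_weighted(p, defn)
  expect_equal(w, 1 / 9, tolerance = 1e-12)

  # intake at 0.4 * p80 of a protective group earns sub-score 0.4
  p2 <- toy_profiles(rep(0, 9))
  p2[hl] <- 2
  p2[hh[1]] <- 0.4 * 2
  expect_equal(score_weighted(p2, defn), 0.4 / 9, tolerance = 1e-12)

  # every group at its best anchor scores the full weight sum of 1
  best <- toy_profiles(rep(0, 9))
  best[hh] <- 2
  expect_equal(score_weighted(best, defn), 1, tolerance = 1e-12)
  expect_equal(score_unweighted(best, defn), 9L)
})

test_that("both scores are monotone in the healthy direction", {
  set.seed(11)
  defn <- toy_definition(median = 0.8, p80 = 1.7)
  tab <- defn$table
  for (rep_i in 1:200) {
    base <- toy_profiles(matrix(rexp(9, 1), 1))
    g <- sample(9, 1)
    up <- base
    up[tab$group[g]] <- up[[tab$group[g]]] + rexp(1, 2)
    sgn <- if (tab$direction[g] == "healthy_high") 1 else -1
    expect_gte(sgn * (score_unweighted(up, defn) -
                        score_unweighted(base, defn)), 0)
    expect_gte(sgn * (score_weighted(up, defn) -
                        score_weighted(base, defn)), -1e-12)
  }
})

test_that("unweighted scores survive monotone transforms of intake scales", {
  set.seed(12)
  x <- rexp(50, 1)
  defn <- toy_definition(median = median(x), p80 = 2)
  prof <- toy_profiles(cbind(x, matrix(1, 50, 8)))
  tr <- function(v) log1p(v) * 3    # strictly increasing
  defn_tr <- defn
  defn_tr$table$median_cutpoint[1] <- tr(defn$table$median_cutpoint[1])
  prof_tr <- prof
  prof_tr[[defn$table$group[1]]] <- tr(prof[[defn$table$group[1]]])
  expect_equal(score_unweighted(prof_tr, defn_tr),
               score_unweighted(prof, defn))
})

test_that("weighted and unweighted scores rank cohorts concordantly", {
  co <- make_fixture_cohort("null", n = 300, seed = 13)
  st <- cohort_stages(co)
  groups <- toy_definition()$table$group
  directions <- tibble::tibble(group = groups,
                               direction = toy_definition()$table$direction)
  contrib <- stats::setNames(seq(19.6, 3.9, length.out = 9), groups)
  defn <- build_definition(st$prof_b, directions, contrib)
  uw <- score_unweighted(st$prof_b, defn)
  w <- score_weighted(st$prof_b, defn)
  expect_true(all(uw >= 0 & uw <= 9))
  expect_true(all(w >= 0 & w <= 1))
  expect_gt(cor(uw, w, method = "spearman"), 0)
})

test_that("cohort scoring freezes the definition and differences visits", {
  st <- tiny_stages()
  defn <- toy_definition(median = 1, p80 = 2)
  same <- score_cohort(st$prof_b, st$prof_b, defn)
  expect_true(all(same$delta_hds == 0))
  expect_true(all(same$delta_whds == 0))

  # crossing one healthy_low group's median downward adds exactly one point
  hl <- defn$table$group[defn$table$direction == "healthy_low"]
  b <- toy_profiles(rep(2, 9))
  f <- b
  f[hl[2]] <- 0.5
  rec <- score_cohort(b, f, defn)
  expect_equal(rec$delta_hds, 1L)

  # a child absent at follow-up has missing follow-up and delta scores
  rec2 <- score_cohort(st$prof_b, st$prof_f[-1, ], defn)
  missing_child <- setdiff(st$prof_b$child_id, st$prof_f$child_id[-1])
  row <- rec2[rec2$child_id == missing_child, ]
  expect_true(is.na(row$hds_followup) && is.na(row$delta_hds))
})

test_that("analysis bands partition the score range", {
  b <- hds_bands(0:9)
  expect_equal(as.character(b),
               c(rep("<=3", 4), "4", "5", "6", "7", ">=8", ">=8"))
  expect_equal(levels(b), c("<=3", "4", "5", "6", "7", ">=8"))
})
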