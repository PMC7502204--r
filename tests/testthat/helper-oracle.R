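# Brute-force oracle implementations, written as plain loops independently
# of the package's vectorized code paths. Used to freeze expected values.

# energy-adjusted profile for one child at one visit
oracle_profile <- function(records, map, child, visit = "baseline") {
  if ("visit" %in% names(records)) {
    records <- records[records$visit == visit, ]
  }
  rec <- records[records$child_id == child, ]
  days <- unique(rec$day)
  g_day <- setNames(numeric(26), food_groups())
  energy_by_day <- numeric(0)
  for (d in days) {
    rd <- rec[rec$day == d, ]
    e <- 0
    for (i in seq_len(nrow(rd))) {
      grp <- map$group[map$item == rd$food_item[i]]
      g_day[grp] <- g_day[grp] + rd$grams[i]
      e <- e + rd$energy_kcal[i]
    }
    energy_by_day <- c(energy_by_day, e)
  }
  g_day <- g_day / length(days)
  energy <- mean(energy_by_day)
  list(energy = energy, g_day = g_day, g100 = 100 * g_day / energy)
}

# pooled sex/age strata replicating the documented rule: merge the smallest
# under-sized age bin with its nearest neighbour (ties toward younger ages)
oracle_strata <- function(ages, sexes, min_n = 20) {
  out <- list()
  for (sx in unique(sexes)) {
    a <- sort(unique(ages[sexes == sx]))
    bins <- lapply(a, function(x) x)
    repeat {
      sizes <- sapply(bins, function(b) sum(sexes == sx & ages %in% b))
      if (length(bins) == 1 || min(sizes) >= min_n) break
      i <- which(sizes == min(sizes))[1]
      cand <- c()
      if (i > 1) cand <- c(cand, i - 1)
      if (i < length(bins)) cand <- c(cand, i + 1)
      gaps <- sapply(cand, function(j) {
        min(abs(rep(bins[[i]], each = length(bins[[j]])) -
                  rep(bins[[j]], times = length(bins[[i]]))))
      })
      j <- cand[which(gaps == min(gaps))[1]]
      lo <- min(i, j); hi <- max(i, j)
      bins[[lo]] <- sort(c(bins[[lo]], bins[[hi]]))
      bins <- bins[-hi]
    }
    for (b in bins) out[[paste(sx, paste0(min(b), "-", max(b)))]] <-
        list(sex = sx, ages = b)
  }
  out
}

# CMRS recomputed from raw panel values by explicit loops
oracle_cmrs <- function(panel, covariates, min_n = 20) {
  ages <- floor(covariates$age[match(panel$child_id, covariates$child_id)])
  sexes <- as.character(
    covariates$sex[match(panel$child_id, covariates$child_id)])
  strata <- oracle_strata(ages, sexes, min_n)
  comp <- list(
    wc = panel$wc,
    bp = (panel$sbp + panel$dbp) / 2,
    glucose = panel$glucose,
    hdl = panel$hdl,
    tg = panel$tg)
  z <- matrix(NA_real_, nrow(panel), 5,
              dimnames = list(NULL, names(comp)))
  for (s in strata) {
    in_s <- sexes == s$sex & ages %in% s$ages
    for (m in names(comp)) {
      v <- comp[[m]][in_s]
      mu <- mean(v, na.rm = TRUE)
      sd_ <- sd(v, na.rm = TRUE)
      z[in_s, m] <- (comp[[m]][in_s] - mu) / sd_
    }
  }
  z[, "wc"] + z[, "bp"] + z[, "glucose"] - z[, "hdl"] + z[, "tg"]
}

oracle_map <- function(sbp, dbp) dbp + 0.33 * (sbp - dbp)
oracle_homa <- function(insulin, glucose_mmol) {
  (insulin * (glucose_mmol * 18.0)) / 405
}
oracle_bmi <- function(weight_kg, height_cm) weight_kg / (height_cm / 100)^2

# diet scores for one profile row, via explicit per-group loops
oracle_hds <- function(profile_row, defn) {
  tab <- defn$table
  uw <- 0L
  w <- 0
  for (i in seq_len(nrow(tab))) {
    x <- profile_row[[tab$group[i]]]
    med <- tab$median_cutpoint[i]
    p80 <- tab$anchor_p80[i]
    frac <- x / p80
    if (frac > 1) frac <- 1
    if (frac < 0) frac <- 0
    if (tab$direction[i] == "healthy_high") {
      if (x > med) uw <- uw + 1L
      w <- w + tab$weight[i] * frac
    } else {
      if (x <= med) uw <- uw + 1L
      w <- w + tab$weight[i] * (1 - frac)
    }
  }
  list(unweighted = uw, weighted = w)
}

# step-up decisions by exhaustively testing every candidate rejection count
oracle_bh <- function(p, q) {
  m <- length(p)
  sorted <- sort(p)
  best_k <- 0
  for (k in seq_len(m)) {
    if (sorted[k] <= k * q / m) best_k <- k
  }
  if (best_k == 0) rep(FALSE, m) else p <= sorted[best_k]
}
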