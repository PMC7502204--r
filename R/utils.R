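# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw n rows from N(0, R) via Cholesky; errors if R is not positive definite.
rmvnorm_chol <- function(n, R) {
  L <- tryCatch(chol(R), error = function(e) {
    stop("correlation block is not positive definite", call. = FALSE)
  })
  matrix(stats::rnorm(n * ncol(R)), n, ncol(R)) %*% L
}

# Exchangeable correlation matrix
exch_cor <- function(d, rho) {
  R <- matrix(rho, d, d)
  diag(R) <- 1
  R
}

# Derive a stage seed from a master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 1009) %% 2147483647L)
}

require_columns <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  abort_if(length(missing) > 0,
           sprintf("%s is missing required column(s): %s",
                   what, paste(missing, collapse = ", ")))
  invisible(df)
}
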