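# Independent brute-force re-implementations used as oracles. These are kept
# deliberately naive and separate from the package code paths they check.

# Greedy p-ranked pruning: repeated full scans over a plain named p vector.
oracle_stepwise <- function(candidates, r, threshold) {
  p <- stats::setNames(candidates$pvalue, candidates$rsid)
  remaining <- candidates$rsid
  selected <- character(0)
  while (length(remaining) > 0) {
    best_p <- min(p[remaining])
    ties <- remaining[p[remaining] == best_p]
    best <- sort(ties)[1]
    selected <- c(selected, best)
    keep <- character(0)
    for (v in remaining) {
      if (v != best && r[best, v]^2 <= threshold) keep <- c(keep, v)
    }
    remaining <- keep
  }
  selected
}

# Interpolated weighted median by explicit segment search.
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  s <- cumsum(ww) - ww / 2
  if (0.5 <= s[1]) return(th[1])
  n <- length(th)
  if (0.5 >= s[n]) return(th[n])
  k <- max(which(s < 0.5))
  th[k] + (th[k + 1] - th[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

# GLS fit of by on bx through the origin with an explicit matrix inverse.
oracle_gls <- function(bx, by, omega) {
  oi <- solve(omega)
  est <- drop(t(bx) %*% oi %*% by) / drop(t(bx) %*% oi %*% bx)
  se <- 1 / sqrt(drop(t(bx) %*% oi %*% bx))
  c(estimate = est, se = se)
}

# Random valid instrument for property tests.
random_instrument <- function(J, seed) {
  withr::with_seed(seed, {
    harmonized_instrument(
      beta_x = stats::runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE),
      se_x = stats::runif(J, 0.005, 0.03),
      beta_y = stats::rnorm(J, 0, 0.1),
      se_y = stats::runif(J, 0.005, 0.05)
    )
  })
}

# Random positive-definite correlation matrix.
random_ld <- function(rsids, seed) {
  n <- length(rsids)
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n * n), n, n)
    r <- stats::cov2cor(crossprod(a) + diag(n) * 0.5)
    ld_matrix(r, rsids)
  })
}

write_tsv_tmp <- function(df, dir = tempdir(), name = NULL) {
  path <- if (is.null(name)) tempfile(fileext = ".tsv", tmpdir = dir)
          else file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
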