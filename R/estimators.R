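# 95% CI multiplier: the exact 0.975 normal quantile, not 1.96.
.z975 <- stats::qnorm(0.975)

# Assemble a full estimate record from (estimate, se). Confidence bounds and
# the two-sided p come from the normal reference unless `df` is supplied.
mr_estimate <- function(method, estimate, se, n_variants, df = NULL) {
  stopifnot(is.finite(estimate), is.finite(se), se > 0)
  if (is.null(df)) {
    half <- .z975 * se
    p <- 2 * stats::pnorm(-abs(estimate / se))
  } else {
    half <- stats::qt(0.975, df) * se
    p <- 2 * stats::pt(-abs(estimate / se), df)
  }
  p <- max(p, .Machine$double.xmin)
  structure(
    list(method = method, estimate = estimate, se = se,
         ci_low = estimate - half, ci_high = estimate + half, pvalue = p,
         odds_ratio = exp(estimate),
         or_ci_low = exp(estimate - half), or_ci_high = exp(estimate + half),
         n_variants = as.integer(n_variants)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s (%d variant%s): estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], OR %.3f, p %s\n",
    x$method, x$n_variants, if (x$n_variants == 1) "" else "s",
    x$estimate, x$se, x$ci_low, x$ci_high, x$odds_ratio, format_pvalue(x$pvalue)))
  invisible(x)
}

#' Single-variant Wald ratio estimate
#'
#' For one variant, the causal effect of the exposure on the outcome is the
#' ratio of the variant-outcome to the variant-exposure association,
#' `beta_y / beta_x`. The default first-order delta-method standard error is
#' `se_y / |beta_x|`; the second-order form adds the exposure-side
#' uncertainty, `sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)`, and
#' is never smaller.
#'
#' @param beta_x,se_x Variant-exposure association and its SE.
#' @param beta_y,se_y Variant-outcome association (log-odds) and its SE.
#' @param delta_order `"first"` (default) or `"second"`.
#' @return An `mr_estimate` with method `"ratio"`.
#' @export
ratio_estimate <- function(beta_x, se_x, beta_y, se_y,
                           delta_order = c("first", "second")) {
  delta_order <- match.arg(delta_order)
  if (!is.finite(beta_x) || beta_x == 0) {
    stop("ratio estimate undefined: beta_x is zero (weak/null instrument)",
         call. = FALSE)
  }
  if (se_x <= 0 || se_y <= 0) stop("standard errors must be > 0", call. = FALSE)
  estimate <- beta_y / beta_x
  se <- switch(delta_order,
    first = se_y / abs(beta_x),
    second = sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  )
  mr_estimate("ratio", estimate, se, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-variant Wald ratios `theta_j = beta_y_j / beta_x_j` with
#' first-order inverse-variance weights `w_j = beta_x_j^2 / se_y_j^2` — an
#' inverse-variance meta-analysis of the ratio estimates, algebraically equal
#' to weighted regression of `beta_y` on `beta_x` through the origin with
#' weights `1 / se_y^2`. With a single variant it reduces exactly to
#' [ratio_estimate()].
#'
#' The fixed-effects SE is `1 / sqrt(sum(w))`. The random-effects option uses
#' a multiplicative overdispersion model: the fixed SE inflated by
#' `max(1, sqrt(Q / (J - 1)))` with `Q = sum(w * (theta - estimate)^2)`.
#'
#' @param instrument An `mr_harmonized` instrument (or any data frame with
#'   `beta_x`, `se_x`, `beta_y`, `se_y`).
#' @param effects_model `"fixed"` (default) or `"random"`.
#' @return An `mr_estimate` with method `"ivw"`.
#' @export
ivw_estimate <- function(instrument, effects_model = c("fixed", "random")) {
  effects_model <- match.arg(effects_model)
  d <- .instrument_frame(instrument, min_variants = 1L)
  theta <- d$beta_y / d$beta_x
  w <- d$beta_x^2 / d$se_y^2
  estimate <- sum(w * theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  J <- nrow(d)
  if (effects_model == "random" && J > 1L) {
    q <- sum(w * (theta - estimate)^2)
    se <- se * max(1, sqrt(q / (J - 1)))
  }
  out <- mr_estimate("ivw", estimate, se, J)
  out$effects_model <- effects_model
  out
}

#' Correlation-aware IVW via generalized least squares
#'
#' When instrument variants are in residual linkage disequilibrium, the
#' outcome betas are correlated and the independence-assuming IVW understates
#' the standard error. This estimator fits the no-intercept regression of
#' `beta_y` on `beta_x` by generalized least squares with covariance
#' `Omega[j, k] = r[j, k] * se_y_j * se_y_k`:
#' `estimate = (bx' Omega^-1 by) / (bx' Omega^-1 bx)`,
#' `se = 1 / sqrt(bx' Omega^-1 bx)`. With an identity LD matrix it equals the
#' fixed-effects [ivw_estimate()].
#'
#' This is opt-in: it is never applied silently by the pipeline.
#'
#' @param instrument An `mr_harmonized` instrument.
#' @param ld An [ld_matrix()] covering every instrument rsid.
#' @param ridge Non-negative fraction of the mean diagonal added to
#'   `Omega`'s diagonal to regularize near-singular matrices. Default 0.
#' @return An `mr_estimate` with method `"ivw_correlated"`.
#' @export
ivw_correlated <- function(instrument, ld, ridge = 0) {
  d <- .instrument_frame(instrument, min_variants = 1L)
  absent <- setdiff(d$rsid, rownames(ld))
  if (length(absent)) {
    stop("instrument rsid(s) missing from LD matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  r <- unclass(ld)[d$rsid, d$rsid, drop = FALSE]
  omega <- r * tcrossprod(d$se_y)
  if (ridge > 0) diag(omega) <- diag(omega) + ridge * mean(diag(omega))
  ch <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(ch)) {
    stop("outcome covariance matrix is singular; consider a small `ridge` ",
         "epsilon or pruning duplicate variants", call. = FALSE)
  }
  oi_bx <- backsolve(ch, forwardsolve(t(ch), d$beta_x))
  oi_by <- backsolve(ch, forwardsolve(t(ch), d$beta_y))
  prec <- sum(d$beta_x * oi_bx)
  estimate <- sum(d$beta_x * oi_by) / prec
  mr_estimate("ivw_correlated", estimate, 1 / sqrt(prec), nrow(d))
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-variant Wald ratios is consistent as long
#' as valid variants contribute at least half the total weight — i.e. up to
#' 50% of the instrument may be invalid (pleiotropic). Ratios are sorted and
#' the estimate is the linear interpolation of the ratio at cumulative
#' midpoint weight 0.5, with first-order inverse-variance weights
#' `beta_x^2 / se_y^2` normalized to sum to one.
#'
#' The standard error comes from a seeded parametric bootstrap: each
#' replicate redraws `beta_x_j ~ N(beta_x_j, se_x_j)` and
#' `beta_y_j ~ N(beta_y_j, se_y_j)` and recomputes the weighted median.
#' Outcome-side perturbations are drawn in antithetic pairs, which lowers
#' bootstrap noise and makes the SE exactly invariant under a global sign
#' flip of the outcome betas.
#'
#' @param instrument An `mr_harmonized` instrument with at least 3 variants.
#' @param n_boot Number of bootstrap replicates (>= 2; rounded up to even).
#'   Default 1000.
#' @param seed Integer seed for the bootstrap; required, so results are never
#'   silently irreproducible.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(instrument, n_boot = 1000, seed) {
  d <- .instrument_frame(instrument, min_variants = 3L,
                         context = "weighted median")
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required for the weighted-median bootstrap", call. = FALSE)
  }
  if (!is.numeric(n_boot) || n_boot < 2) {
    stop("n_boot must be at least 2", call. = FALSE)
  }
  estimate <- .weighted_median_point(d$beta_y / d$beta_x,
                                     d$beta_x^2 / d$se_y^2)
  J <- nrow(d)
  half <- ceiling(n_boot / 2)
  boot <- withr::with_seed(as.integer(seed), {
    zx <- matrix(stats::rnorm(half * J), half, J)
    zy <- matrix(stats::rnorm(half * J), half, J)
    one <- function(zxi, zyi) {
      bx <- d$beta_x + d$se_x * zxi
      by <- d$beta_y + d$se_y * zyi
      .weighted_median_point(by / bx, bx^2 / d$se_y^2)
    }
    ests <- numeric(2 * half)
    for (i in seq_len(half)) {
      ests[2 * i - 1] <- one(zx[i, ], zy[i, ])
      ests[2 * i] <- one(zx[i, ], -zy[i, ])  # antithetic outcome draw
    }
    ests
  })
  out <- mr_estimate("weighted_median", estimate, stats::sd(boot), J)
  out$n_boot <- 2L * half
  out
}

# Interpolated weighted median: cumulative midpoint weights
# s_j = cumsum(w)_j - w_j / 2 on the sorted ratios, evaluated at s = 0.5.
.weighted_median_point <- function(theta, w) {
  ord <- order(theta)
  theta <- theta[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  stats::approx(s, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome betas on the exposure betas with
#' a free intercept and weights `1 / se_y^2`. Each variant is first oriented
#' so that `beta_x >= 0` (flipping both betas where needed). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect per variant, and a nonzero intercept is
#' evidence of directional pleiotropy. Standard errors are inflated by the
#' multiplicative overdispersion factor `max(1, sqrt(RSS / (J - 2)))` on the
#' weighted residual sum of squares; p-values use the standard normal by
#' default (`p_reference = "t"` switches to the t with J - 2 df).
#'
#' @param instrument An `mr_harmonized` instrument with at least 3 variants.
#' @param p_reference `"normal"` (default) or `"t"`.
#' @param fit_intercept Fit the pleiotropy intercept (default `TRUE`).
#'   With `FALSE` (and `overdispersion = FALSE`) the fit collapses to the
#'   fixed-effects IVW regression through the origin.
#' @param overdispersion Apply the `max(1, sqrt(RSS/df))` SE scaling
#'   (default `TRUE`).
#' @return An object of class `mr_egger`: list with `slope` (an
#'   `mr_estimate`, method `"egger_slope"`), `intercept_estimate`,
#'   `intercept_se`, `intercept_pvalue`.
#' @export
egger_regression <- function(instrument, p_reference = c("normal", "t"),
                             fit_intercept = TRUE, overdispersion = TRUE) {
  p_reference <- match.arg(p_reference)
  min_j <- if (fit_intercept) 3L else 1L
  d <- .instrument_frame(instrument, min_variants = min_j,
                         context = "MR-Egger regression")
  # orient per-variant so the exposure effect is non-negative
  flip <- sign(d$beta_x)
  bx <- d$beta_x * flip
  by <- d$beta_y * flip
  w <- 1 / d$se_y^2
  J <- nrow(d)
  if (fit_intercept && stats::sd(bx) < 1e-12) {
    stop("degenerate design: all exposure betas equal after orientation",
         call. = FALSE)
  }
  x <- if (fit_intercept) cbind(intercept = 1, slope = bx) else cbind(slope = bx)
  xtwx <- crossprod(x, w * x)
  coef <- solve(xtwx, crossprod(x, w * by))[, 1]
  resid <- by - x %*% coef
  dfree <- J - ncol(x)
  scale <- 1
  if (overdispersion && dfree > 0) {
    scale <- max(1, sqrt(sum(w * resid^2) / dfree))
  }
  ses <- sqrt(diag(solve(xtwx))) * scale
  tdf <- if (p_reference == "t") dfree else NULL
  slope <- mr_estimate("egger_slope", coef[["slope"]], ses[["slope"]], J,
                       df = tdf)
  if (!fit_intercept) {
    return(structure(list(slope = slope, intercept_estimate = 0,
                          intercept_se = NA_real_,
                          intercept_pvalue = NA_real_),
                     class = "mr_egger"))
  }
  iz <- coef[["intercept"]] / ses[["intercept"]]
  ip <- if (is.null(tdf)) 2 * stats::pnorm(-abs(iz)) else 2 * stats::pt(-abs(iz), tdf)
  structure(
    list(slope = slope,
         intercept_estimate = coef[["intercept"]],
         intercept_se = ses[["intercept"]],
         intercept_pvalue = max(ip, .Machine$double.xmin)),
    class = "mr_egger"
  )
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  if (!is.na(x$intercept_se)) {
    cat(sprintf("  intercept %.4f (se %.4f), p %s\n", x$intercept_estimate,
                x$intercept_se, format_pvalue(x$intercept_pvalue)))
  }
  invisible(x)
}

# Common validation for estimator inputs.
.instrument_frame <- function(instrument, min_variants = 1L,
                              context = "estimation") {
  d <- tibble::as_tibble(instrument)
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(d))) {
    stop("instrument must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!("rsid" %in% names(d))) d$rsid <- sprintf("snp_%d", seq_len(nrow(d)))
  if (nrow(d) < min_variants) {
    stop(sprintf("%s requires at least %d variant(s), got %d",
                 context, min_variants, nrow(d)), call. = FALSE)
  }
  if (any(d$se_x <= 0) || any(d$se_y <= 0)) {
    stop("standard errors must be > 0", call. = FALSE)
  }
  zero <- d$rsid[d$beta_x == 0]
  if (length(zero)) {
    stop("beta_x is zero for variant(s): ", paste(zero, collapse = ", "),
         call. = FALSE)
  }
  d
}
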