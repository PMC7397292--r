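test_that("Wald ratio reproduces the packaged single-variant worked example", {
  est <- ratio_estimate(beta_x = -0.058, se_x = 0.01,
                        beta_y = 0.0439, se_y = 0.0128)
  expect_equal(round(est$estimate, 3), -0.757)
  expect_equal(round(est$se, 3), 0.221)
  expect_equal(round(est$odds_ratio, 3), 0.469)
  expect_equal(round(est$pvalue, 3), 0.001)
  expect_equal(est$odds_ratio, exp(est$estimate))

  ident <- ratio_estimate(0.5, 0.05, 0.5, 0.1)
  expect_equal(ident$estimate, 1.0)
  expect_equal(ident$se, 0.2)

  expect_error(ratio_estimate(0, 0.01, 0.1, 0.01), "beta_x")
})

test_that("second-order ratio SE is never below first-order", {
  withr::with_seed(42, {
    for (i in 1:1000) {
      bx <- stats::runif(1, -0.5, 0.5)
      if (bx == 0) next
      sx <- stats::runif(1, 1e-4, 0.1)
      by <- stats::rnorm(1, 0, 0.2)
      sy <- stats::runif(1, 1e-4, 0.1)
      e1 <- ratio_estimate(bx, sx, by, sy, "first")
      e2 <- ratio_estimate(bx, sx, by, sy, "second")
      expect_gte(e2$se, e1$se)
      expect_equal(e1$estimate, e2$estimate)
    }
  })
})

test_that("IVW reduces to the ratio for one variant and pools equal variants", {
  h1 <- harmonized_instrument(-0.058, 0.01, 0.0439, 0.0128)
  ivw1 <- ivw_estimate(h1)
  rat <- ratio_estimate(-0.058, 0.01, 0.0439, 0.0128)
  expect_equal(ivw1$estimate, rat$estimate)
  expect_equal(ivw1$se, rat$se)

  h2 <- harmonized_instrument(c(0.1, 0.1), c(0.01, 0.01),
                              c(0.05, 0.05), c(0.02, 0.02))
  ivw2 <- ivw_estimate(h2)
  expect_equal(ivw2$estimate, 0.5)
  expect_equal(ivw2$se, ivw_estimate(h2[1, ])$se / sqrt(2))
})

test_that("IVW ratio-pooling equals weighted regression through the origin", {
  for (seed in 1:200) {
    h <- random_instrument(withr::with_seed(seed, sample(2:30, 1)), seed)
    ours <- ivw_estimate(h)
    fit <- stats::lm(beta_y ~ beta_x - 1, data = h, weights = 1 / h$se_y^2)
    expect_equal(ours$estimate, unname(stats::coef(fit)), tolerance = 1e-12)
  }
})

test_that("random-effects IVW inflates but never deflates the fixed SE", {
  for (seed in 1:50) {
    h <- random_instrument(10, 1000 + seed)
    fx <- ivw_estimate(h, "fixed")
    rx <- ivw_estimate(h, "random")
    expect_equal(fx$estimate, rx$estimate)
    expect_gte(rx$se, fx$se)
  }
})

test_that("correlation-aware IVW matches diagonal and duplicate limits", {
  h <- random_instrument(8, 7)
  ident <- ld_matrix(diag(8), h$rsid)
  expect_equal(ivw_correlated(h, ident)$estimate, ivw_estimate(h)$estimate,
               tolerance = 1e-10)
  expect_equal(ivw_correlated(h, ident)$se, ivw_estimate(h)$se,
               tolerance = 1e-10)

  # two near-duplicate variants: SE approaches the single-variant SE
  h1 <- harmonized_instrument(0.1, 0.01, 0.05, 0.02)
  h2 <- harmonized_instrument(c(0.1, 0.1), c(0.01, 0.01),
                              c(0.05, 0.05), c(0.02, 0.02),
                              rsid = c("a", "b"))
  r <- matrix(c(1, 1 - 1e-10, 1 - 1e-10, 1), 2)
  dup <- ivw_correlated(h2, ld_matrix(r, c("a", "b")))
  expect_equal(dup$se, ivw_estimate(h1)$se, tolerance = 1e-4)

  # exact duplicates make the covariance singular
  rsing <- matrix(c(1, 1, 1, 1), 2)
  expect_error(ivw_correlated(h2, ld_matrix(rsing, c("a", "b"))), "ridge")
  ok <- ivw_correlated(h2, ld_matrix(rsing, c("a", "b")), ridge = 1e-6)
  expect_true(is.finite(ok$estimate))

  expect_error(ivw_correlated(h2, ld_matrix(diag(1), "a")), "b")
})

test_that("correlation-aware IVW matches a brute-force GLS solve", {
  for (seed in 1:50) {
    h <- random_instrument(5, 2000 + seed)
    ld <- random_ld(h$rsid, 3000 + seed)
    omega <- unclass(ld) * tcrossprod(h$se_y)
    ours <- ivw_correlated(h, ld)
    ref <- oracle_gls(h$beta_x, h$beta_y, omega)
    expect_equal(ours$estimate, unname(ref["estimate"]), tolerance = 1e-8)
    expect_equal(ours$se, unname(ref["se"]), tolerance = 1e-8)
  }
})

test_that("weighted median interpolates the 50% weight point", {
  # constant ratios: estimate equals the constant regardless of weights
  hc <- harmonized_instrument(c(0.1, 0.2, 0.4), c(0.01, 0.01, 0.01),
                              0.3 * c(0.1, 0.2, 0.4), c(0.01, 0.03, 0.02))
  expect_equal(weighted_median(hc, 100, seed = 1)$estimate, 0.3)

  # equal weights, ratios (0.1, 0.2, 0.9): the midpoint interpolation gives 0.2
  he <- harmonized_instrument(c(0.1, 0.1, 0.1), c(0.01, 0.01, 0.01),
                              c(0.01, 0.02, 0.09), c(0.02, 0.02, 0.02))
  expect_equal(weighted_median(he, 100, seed = 1)$estimate, 0.2)

  expect_error(weighted_median(hc[1:2, ], 100, seed = 1), "3 variant")
  expect_error(weighted_median(hc, 1, seed = 1), "n_boot")
  expect_error(weighted_median(hc, 100), "seed")
})

test_that("weighted median stays within the ratio range and matches its oracle", {
  for (seed in 1:100) {
    h <- random_instrument(withr::with_seed(seed, sample(3:25, 1)), 5000 + seed)
    theta <- h$beta_y / h$beta_x
    w <- h$beta_x^2 / h$se_y^2
    est <- weighted_median(h, 50, seed = seed)$estimate
    expect_gte(est, min(theta))
    expect_lte(est, max(theta))
    expect_equal(est, oracle_weighted_median(theta, w), tolerance = 1e-12)
  }
})

test_that("weighted median bootstrap is seeded and reproducible", {
  h <- random_instrument(10, 77)
  a <- weighted_median(h, 200, seed = 9)
  b <- weighted_median(h, 200, seed = 9)
  c <- weighted_median(h, 200, seed = 10)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
})

test_that("MR-Egger recovers an exact linear relationship", {
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.5 * bx + 0.1
  h <- harmonized_instrument(bx, rep(0.01, 3), by, c(0.01, 0.02, 0.015))
  eg <- egger_regression(h)
  expect_equal(eg$slope$estimate, 0.5, tolerance = 1e-10)
  expect_equal(eg$intercept_estimate, 0.1, tolerance = 1e-10)

  # orientation: flipping a variant's allele coding must not change the fit
  h2 <- harmonized_instrument(c(-0.1, 0.2, 0.3), rep(0.01, 3),
                              c(-by[1], by[2], by[3]), c(0.01, 0.02, 0.015))
  eg2 <- egger_regression(h2)
  expect_equal(eg2$slope$estimate, eg$slope$estimate)
  expect_equal(eg2$intercept_estimate, eg$intercept_estimate)

  expect_error(egger_regression(h[1:2, ]), "3 variant")
  hdeg <- harmonized_instrument(c(0.1, 0.1, -0.1), rep(0.01, 3),
                                c(0.05, 0.06, 0.04), rep(0.01, 3))
  expect_error(egger_regression(hdeg), "degenerate")
})

test_that("Egger constrained through the origin reproduces fixed-effects IVW", {
  for (seed in 1:50) {
    h <- random_instrument(8, 8000 + seed)
    eg <- egger_regression(h, fit_intercept = FALSE, overdispersion = FALSE)
    ivw <- ivw_estimate(h, "fixed")
    expect_equal(eg$slope$estimate, ivw$estimate, tolerance = 1e-10)
    expect_equal(eg$slope$se, ivw$se, tolerance = 1e-10)
  }
})

test_that("odds ratios are the exact exponential of the log-odds scale", {
  for (seed in 1:50) {
    h <- random_instrument(6, 9000 + seed)
    for (est in list(ivw_estimate(h), weighted_median(h, 50, seed = seed),
                     egger_regression(h)$slope)) {
      expect_identical(est$odds_ratio, exp(est$estimate))
      expect_identical(est$or_ci_low, exp(est$ci_low))
      expect_identical(est$or_ci_high, exp(est$ci_high))
      expect_true(est$ci_low <= est$estimate && est$estimate <= est$ci_high)
      expect_gt(est$pvalue, 0)
      expect_lte(est$pvalue, 1)
    }
  }
})

test_that("negating all outcome betas flips estimates, leaves SEs and p-values", {
  for (seed in 1:20) {
    h <- random_instrument(9, 600 + seed)
    hneg <- harmonized_instrument(h$beta_x, h$se_x, -h$beta_y, h$se_y,
                                  rsid = h$rsid)
    pairs <- list(
      list(ivw_estimate(h), ivw_estimate(hneg)),
      list(ivw_estimate(h, "random"), ivw_estimate(hneg, "random")),
      list(weighted_median(h, 100, seed = seed),
           weighted_median(hneg, 100, seed = seed)),
      list(egger_regression(h)$slope, egger_regression(hneg)$slope)
    )
    for (pr in pairs) {
      expect_equal(pr[[2]]$estimate, -pr[[1]]$estimate, tolerance = 1e-12)
      expect_equal(pr[[2]]$se, pr[[1]]$se, tolerance = 1e-12)
      expect_equal(pr[[2]]$pvalue, pr[[1]]$pvalue, tolerance = 1e-12)
    }
    e1 <- egger_regression(h)
    e2 <- egger_regression(hneg)
    expect_equal(e2$intercept_estimate, -e1$intercept_estimate, tolerance = 1e-12)
    expect_equal(e2$intercept_pvalue, e1$intercept_pvalue, tolerance = 1e-12)
  }
})

test_that("report rows format the odds scale the way results tables print it", {
  est <- ratio_estimate(-0.058, 0.01, 0.0439, 0.0128)
  row <- to_report_row(est, "Gout", "JMJD1C")
  expect_equal(row$or_display, "0.469")
  expect_equal(row$estimate_se_display, "-0.757 (0.221)")
  expect_equal(row$p_display, "0.001")
  expect_true(row$significant)

  null_est <- mrpipe::ivw_estimate(
    harmonized_instrument(c(0.1, 0.2), c(0.01, 0.01), c(0, 0), c(0.1, 0.1)))
  expect_equal(to_report_row(null_est, "x", "y")$or_display, "1.000")

  strong <- harmonized_instrument(c(0.1, 0.2, 0.3), rep(0.01, 3),
                                  0.285 * c(0.1, 0.2, 0.3), rep(0.001, 3))
  expect_equal(to_report_row(ivw_estimate(strong), "RA", "SHBG")$p_display,
               "<0.001")

  eg <- egger_regression(random_instrument(6, 3))
  erow <- to_report_row(eg, "x", "y")
  expect_equal(erow$method, "egger_slope")
  expect_false(is.na(erow$egger_intercept))
})
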