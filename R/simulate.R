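#' Configuration for the two-sample summary-statistic generator
#'
#' Defaults emulate the study conditions the packaged testosterone fixtures
#' come from: an exposure GWAS of a few thousand individuals (n = 3225),
#' outcome GWAS of a few hundred thousand, per-variant
#' exposure effects spanning the magnitudes seen in the packaged instruments
#' (|beta| between 0.033 and 0.181), and common variants (MAF 0.05-0.5).
#'
#' @param n_variants Number of instrument variants.
#' @param theta True causal effect, log-odds per exposure unit.
#' @param gamma_range Range of true exposure-effect magnitudes (uniform draw;
#'   each variant gets a random sign).
#' @param maf_range Range of minor-allele frequencies, within (0, 0.5].
#' @param n_exposure,n_outcome Effective sample sizes; per-variant SEs follow
#'   `1 / sqrt(2 p (1 - p) n)`.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects) or
#'   `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_mean,pleiotropy_sd Normal parameters of the pleiotropic
#'   effect given to invalid variants.
#' @param invalid_fraction Fraction of variants given a pleiotropic effect,
#'   in \[0, 1\].
#' @param seed Integer seed; required (no global random state is consumed).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 20, theta = 0,
                       gamma_range = c(0.033, 0.181),
                       maf_range = c(0.05, 0.5),
                       n_exposure = 3225, n_outcome = 3e5,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0.02,
                       invalid_fraction = 0, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed) || is.null(seed)) stop("`seed` is required", call. = FALSE)
  stopifnot(n_variants >= 1, n_exposure >= 1, n_outcome >= 1)
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    stop("invalid_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  }
  if (gamma_range[1] <= 0 || gamma_range[1] > gamma_range[2]) {
    stop("gamma_range must be positive and ordered", call. = FALSE)
  }
  structure(
    list(n_variants = as.integer(n_variants), theta = theta,
         gamma_range = gamma_range, maf_range = maf_range,
         n_exposure = n_exposure, n_outcome = n_outcome,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         invalid_fraction = invalid_fraction, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Non-palindromic ordered allele pairs (effect, other).
.allele_pairs <- rbind(
  c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
  c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T")
)

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Draws summary-level data directly: for variant j with MAF `p_j` and true
#' exposure effect `gamma_j`, the observed exposure association is
#' `beta_x_j ~ N(gamma_j, se_x_j)` with
#' `se_x_j = 1 / sqrt(2 p_j (1 - p_j) n_exposure)`; the outcome association is
#' `beta_y_j ~ N(theta * gamma_j + sign(gamma_j) * alpha_j, se_y_j)` with the
#' analogous outcome-sample SE, where `alpha_j` is the variant's pleiotropic
#' effect (zero for valid variants). The pleiotropic effect acts per
#' exposure-increasing allele — the orientation under which "directional"
#' pleiotropy is defined and the MR-Egger intercept is interpreted — so it is
#' invariant to the arbitrary allele coding of each variant. The two samples
#' are independent, as in two-sample MR. Allele pairs avoid palindromes so
#' the default harmonization policy retains every variant.
#'
#' @param config A [sim_config()].
#' @return A list with `exposure` and `outcome` association tibbles sharing
#'   rsids and alleles, and `truth`: a list with `theta`, per-variant `gamma`,
#'   `alpha`, `maf`, and the logical `invalid` mask.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_variants
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    gamma <- stats::runif(n, config$gamma_range[1], config$gamma_range[2]) *
      sample(c(-1, 1), n, replace = TRUE)
    n_invalid <- round(config$invalid_fraction * n)
    invalid <- rep(FALSE, n)
    invalid[sample.int(n, n_invalid)] <- TRUE
    alpha <- rep(0, n)
    if (config$pleiotropy_mode != "none" && n_invalid > 0) {
      mu <- if (config$pleiotropy_mode == "directional") config$pleiotropy_mean else 0
      alpha[invalid] <- stats::rnorm(n_invalid, mu, config$pleiotropy_sd)
    }
    se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * config$n_outcome)
    beta_x <- stats::rnorm(n, gamma, se_x)
    beta_y <- stats::rnorm(n, config$theta * gamma + sign(gamma) * alpha, se_y)
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), n, replace = TRUE), ,
                          drop = FALSE]
    base <- tibble::tibble(
      rsid = sprintf("rs%07d", seq_len(n)),
      position = seq_len(n) * 1000L,
      effect_allele = pair[, 1], other_allele = pair[, 2]
    )
    assoc <- function(beta, s) {
      out <- base
      out$beta <- beta
      out$se <- s
      out$pvalue <- pmax(2 * stats::pnorm(-abs(beta / s)), .Machine$double.xmin)
      out$eaf <- maf
      out
    }
    list(
      exposure = assoc(beta_x, se_x),
      outcome = assoc(beta_y, se_y),
      truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                   maf = maf, invalid = invalid)
    )
  })
}

#' Simulate a block-correlated candidate set for pruning tests
#'
#' Builds a candidate association list plus a block-diagonal LD matrix with
#' constant signed correlation `within_r` inside each block and zero across
#' blocks. By construction, stepwise pruning at any r-squared threshold below
#' `within_r^2` must keep exactly one variant per block — the block's
#' minimum-p candidate — giving a known ground truth.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size Variants per block (recycled to `n_blocks`).
#' @param within_r Within-block LD correlation, in \[0, 1).
#' @param seed Integer seed.
#' @return A list with `candidates` (association tibble), `ld` (an
#'   [ld_matrix()]) and `blocks` (block index per candidate).
#' @export
simulate_ld_candidates <- function(n_blocks, block_size, within_r, seed) {
  if (within_r < 0 || within_r >= 1) stop("within_r must lie in [0, 1)", call. = FALSE)
  if (n_blocks < 1 || any(block_size < 1)) {
    stop("need at least one block of at least one variant", call. = FALSE)
  }
  sizes <- rep_len(as.integer(block_size), n_blocks)
  n <- sum(sizes)
  withr::with_seed(as.integer(seed), {
    beta <- stats::runif(n, 0.03, 0.18) * sample(c(-1, 1), n, replace = TRUE)
    se <- stats::runif(n, 0.01, 0.04)
    pair <- .allele_pairs[sample.int(nrow(.allele_pairs), n, replace = TRUE), ,
                          drop = FALSE]
    candidates <- tibble::tibble(
      rsid = sprintf("rs%03d", seq_len(n)),
      position = seq_len(n) * 500L,
      effect_allele = pair[, 1], other_allele = pair[, 2],
      beta = beta, se = se,
      pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
    )
    blocks <- rep(seq_len(n_blocks), sizes)
    r <- outer(blocks, blocks, function(a, b) ifelse(a == b, within_r, 0))
    diag(r) <- 1
    list(candidates = candidates,
         ld = ld_matrix(r, candidates$rsid),
         blocks = blocks)
  })
}
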