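.complement <- c(A = "T", T = "A", C = "G", G = "C")

#' Is a variant palindromic?
#'
#' A palindromic variant carries strand-complementary alleles (A/T or C/G),
#' so its strand orientation cannot be inferred from the alleles alone.
#'
#' @param effect_allele,other_allele Character vectors of single A/C/G/T
#'   alleles.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(.complement[effect_allele] == other_allele)
}

#' Harmonize exposure and outcome associations onto a shared effect allele
#'
#' Two-sample MR requires that the variant-exposure and variant-outcome betas
#' refer to the same allele. Variants are matched by rsid; for each match the
#' outcome record is re-oriented to the exposure's effect allele:
#'
#' * same effect/other alleles: kept as-is;
#' * alleles swapped: outcome beta sign-flipped (and `eaf` mirrored);
#' * alleles on the opposite strand (complement, or swapped complement):
#'   complemented, then the same two rules applied;
#' * anything else (e.g. a third allele): dropped with reason
#'   `"allele_mismatch"`.
#'
#' Palindromic variants (A/T or C/G) are ambiguous under strand flips; the
#' default policy drops them. Variants present in only one table are dropped
#' with reason `"unmatched"`. Every dropped variant appears in the drop log:
#' harmonization never silently discards data.
#'
#' @param exposure,outcome Association tibbles (see [read_associations()]).
#' @param palindromic_policy `"drop"` (default) or `"keep"`. Under `"keep"` a
#'   palindromic variant is aligned assuming both studies report the same
#'   strand (only direct/swap matching, no complementing).
#' @return A tibble of class `mr_harmonized` with columns `rsid`, `position`,
#'   `effect_allele`, `other_allele` (the exposure orientation), `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, ordered as in `exposure`. Attributes:
#'   `n_dropped` (count) and `drop_log` (tibble `rsid`, `reason`).
#' @export
harmonize <- function(exposure, outcome, palindromic_policy = c("drop", "keep")) {
  palindromic_policy <- match.arg(palindromic_policy)
  exposure <- validate_associations(exposure)
  outcome <- validate_associations(outcome)

  idx <- match(exposure$rsid, outcome$rsid)
  reasons <- character(0)
  rsids <- character(0)
  drop <- function(rsid, why) {
    rsids <<- c(rsids, rsid)
    reasons <<- c(reasons, why)
  }

  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    j <- idx[i]
    if (is.na(j)) {
      drop(ex$rsid, "unmatched")
      next
    }
    ou <- outcome[j, ]
    if (is_palindromic(ex$effect_allele, ex$other_allele) &&
        palindromic_policy == "drop") {
      drop(ex$rsid, "palindromic")
      next
    }
    aligned <- .align_outcome(ex$effect_allele, ex$other_allele,
                              ou$effect_allele, ou$other_allele,
                              allow_strand_flip = !is_palindromic(ex$effect_allele,
                                                                  ex$other_allele))
    if (is.na(aligned)) {
      drop(ex$rsid, "allele_mismatch")
      next
    }
    rows[[i]] <- tibble::tibble(
      rsid = ex$rsid, position = ex$position,
      effect_allele = ex$effect_allele, other_allele = ex$other_allele,
      beta_x = ex$beta, se_x = ex$se,
      beta_y = aligned * ou$beta, se_y = ou$se
    )
  }

  drop_log <- tibble::tibble(rsid = rsids, reason = reasons)
  kept <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(kept) || nrow(kept) == 0L) {
    stop("no variants survived harmonization; estimation is impossible",
         call. = FALSE)
  }
  new_harmonized(kept, drop_log)
}

# Orientation of the outcome beta relative to the exposure effect allele:
# +1 (same), -1 (swapped) or NA (irreconcilable).
.align_outcome <- function(ea_x, oa_x, ea_y, oa_y, allow_strand_flip = TRUE) {
  if (ea_y == ea_x && oa_y == oa_x) return(1)
  if (ea_y == oa_x && oa_y == ea_x) return(-1)
  if (allow_strand_flip) {
    ea_f <- unname(.complement[ea_y])
    oa_f <- unname(.complement[oa_y])
    if (ea_f == ea_x && oa_f == oa_x) return(1)
    if (ea_f == oa_x && oa_f == ea_x) return(-1)
  }
  NA_real_
}

new_harmonized <- function(tbl, drop_log = tibble::tibble(rsid = character(0),
                                                          reason = character(0))) {
  stopifnot(all(c("rsid", "beta_x", "se_x", "beta_y", "se_y") %in% names(tbl)))
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "n_dropped") <- nrow(drop_log)
  attr(tbl, "drop_log") <- drop_log
  class(tbl) <- c("mr_harmonized", class(tbl))
  tbl
}

#' Construct a harmonized instrument directly from beta/SE vectors
#'
#' Convenience constructor for simulation studies and tests where both tables
#' are already expressed per the same effect allele.
#'
#' @param beta_x,se_x Exposure associations and standard errors.
#' @param beta_y,se_y Outcome associations and standard errors.
#' @param rsid Optional variant identifiers (defaults to `snp_1`, `snp_2`, ...).
#' @return An `mr_harmonized` tibble.
#' @export
harmonized_instrument <- function(beta_x, se_x, beta_y, se_y, rsid = NULL) {
  n <- length(beta_x)
  stopifnot(length(se_x) == n, length(beta_y) == n, length(se_y) == n)
  if (any(se_x <= 0) || any(se_y <= 0)) stop("standard errors must be > 0", call. = FALSE)
  rsid <- rsid %||% sprintf("snp_%d", seq_len(n))
  new_harmonized(tibble::tibble(
    rsid = rsid, position = NA_integer_,
    effect_allele = NA_character_, other_allele = NA_character_,
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y
  ))
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized instrument: %d variant(s), %d dropped\n",
              nrow(x), attr(x, "n_dropped")))
  log <- attr(x, "drop_log")
  if (!is.null(log) && nrow(log)) {
    tab <- table(log$reason)
    cat("  drops:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Split a harmonized instrument back into two association tables
#'
#' Returns per-trait association tibbles in the harmonized (exposure-allele)
#' orientation. Useful for checking that harmonization is idempotent and for
#' writing harmonized data back to disk.
#'
#' @param h An `mr_harmonized` tibble.
#' @return A list with elements `exposure` and `outcome`.
#' @export
harmonized_sides <- function(h) {
  stopifnot(inherits(h, "mr_harmonized"))
  side <- function(beta, se) tibble::tibble(
    rsid = h$rsid, position = h$position,
    effect_allele = h$effect_allele, other_allele = h$other_allele,
    beta = beta, se = se,
    pvalue = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin)
  )
  list(exposure = side(h$beta_x, h$se_x), outcome = side(h$beta_y, h$se_y))
}
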