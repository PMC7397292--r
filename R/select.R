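#' Greedy p-value-ranked stepwise LD pruning
#'
#' Builds a genetic instrument from a candidate variant list the way
#' instruments are clumped in MR practice: pick the remaining candidate with
#' the smallest association p-value, remove every remaining candidate in
#' linkage disequilibrium with it (r-squared strictly greater than
#' `r2_threshold`), and repeat until no candidates remain. The survivors have
#' low pairwise correlations by construction.
#'
#' Pairs at exactly the threshold are retained (the rule removes r² strictly
#' above it). Ties on p-value are broken by lexicographic rsid order, so the
#' result does not depend on input order.
#'
#' @param candidates Association tibble of candidate variants (see
#'   [read_associations()]).
#' @param ld An [ld_matrix()] covering every candidate rsid.
#' @param r2_threshold Pruning threshold on r-squared, in (0, 1]. Default 0.40.
#' @return An object of class `mr_selection`: a list with `selected` (rsids in
#'   selection order), `removed` (named character vector mapping each removed
#'   rsid to the stronger selected rsid that excluded it), and `r2_threshold`.
#' @export
stepwise_select <- function(candidates, ld, r2_threshold = 0.40) {
  candidates <- validate_associations(candidates)
  if (nrow(candidates) == 0L) stop("no candidate variants", call. = FALSE)
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      r2_threshold <= 0 || r2_threshold > 1) {
    stop("r2_threshold must lie in (0, 1]", call. = FALSE)
  }
  absent <- setdiff(candidates$rsid, rownames(ld))
  if (length(absent)) {
    stop("candidate(s) absent from LD matrix: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }

  # deterministic ranking: ascending p, ties by rsid
  ord <- order(candidates$pvalue, candidates$rsid)
  queue <- candidates$rsid[ord]
  r2 <- unclass(ld)[queue, queue, drop = FALSE]^2

  selected <- character(0)
  removed <- character(0)
  removed_by <- character(0)
  while (length(queue)) {
    pick <- queue[1L]
    selected <- c(selected, pick)
    rest <- queue[-1L]
    hit <- rest[r2[pick, rest] > r2_threshold]
    if (length(hit)) {
      removed <- c(removed, hit)
      removed_by <- c(removed_by, rep(pick, length(hit)))
    }
    queue <- setdiff(rest, hit)
  }
  structure(
    list(selected = selected,
         removed = stats::setNames(removed_by, removed),
         r2_threshold = r2_threshold),
    class = "mr_selection"
  )
}

#' @export
print.mr_selection <- function(x, ...) {
  cat(sprintf("Stepwise LD pruning (r^2 > %g removed): %d selected, %d removed\n",
              x$r2_threshold, length(x$selected), length(x$removed)))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Selection result as a removal-log tibble
#'
#' @param x An `mr_selection`.
#' @return Tibble with columns `rsid`, `status` (`selected`/`removed`),
#'   `selection_order` (NA for removed variants) and `removed_by`.
#' @export
selection_log <- function(x) {
  stopifnot(inherits(x, "mr_selection"))
  tibble::tibble(
    rsid = c(x$selected, names(x$removed)),
    status = rep(c("selected", "removed"),
                 c(length(x$selected), length(x$removed))),
    selection_order = c(seq_along(x$selected),
                        rep(NA_integer_, length(x$removed))),
    removed_by = c(rep(NA_character_, length(x$selected)),
                   unname(x$removed))
  )
}
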