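#' Construct and validate an LD matrix
#'
#' Pairwise linkage disequilibrium is stored as signed correlations r (the
#' pruning threshold is applied to r squared). The matrix must be symmetric
#' with unit diagonal, entries in \[-1, 1\], and positive semi-definite within
#' numerical tolerance.
#'
#' @param r Square numeric matrix of signed LD correlations.
#' @param rsids Variant identifiers; defaults to `rownames(r)`.
#' @param tol Symmetry/PSD tolerance.
#' @return A validated `ld_matrix` (a base matrix with dimnames and class).
#' @export
ld_matrix <- function(r, rsids = rownames(r), tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(rsids) || length(rsids) != nrow(r)) {
    stop("LD matrix needs one rsid per row", call. = FALSE)
  }
  if (anyDuplicated(rsids)) stop("duplicate rsids in LD matrix", call. = FALSE)
  storage.mode(r) <- "double"
  if (any(!is.finite(r))) stop("LD matrix has non-finite entries", call. = FALSE)
  if (max(abs(r - t(r))) > tol) {
    stop("LD matrix is asymmetric beyond tolerance ", format(tol), call. = FALSE)
  }
  r <- (r + t(r)) / 2
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1", call. = FALSE)
  diag(r) <- 1
  if (max(abs(r)) > 1 + tol) {
    stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-6) {
    stop("LD matrix is not positive semi-definite (min eigenvalue ",
         format(ev), ")", call. = FALSE)
  }
  dimnames(r) <- list(rsids, rsids)
  class(r) <- c("ld_matrix", class(r))
  r
}

#' Read an LD matrix from a TSV file
#'
#' Two layouts are auto-detected from the header shape: a square labeled
#' matrix (first column = row labels, remaining columns = variants), or long
#'-format triples `rsid_a  rsid_b  r`. Long format is symmetrized; pairs not
#' listed default to r = 0 and the diagonal to 1.
#'
#' @param path Path to a tab-delimited file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("LD file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  is_long <- ncol(df) == 3L && is.character(df[[1]]) && is.character(df[[2]]) &&
    is.numeric(df[[3]])
  if (is_long) {
    a <- df[[1]]; b <- df[[2]]; v <- df[[3]]
    ids <- sort(unique(c(a, b)))
    r <- diag(1, length(ids))
    dimnames(r) <- list(ids, ids)
    for (k in seq_along(v)) {
      r[a[k], b[k]] <- v[k]
      r[b[k], a[k]] <- v[k]
    }
    return(ld_matrix(r, ids))
  }
  rsids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(m), rsids)) {
    stop("row and column variant labels disagree", call. = FALSE)
  }
  ld_matrix(m, rsids)
}

#' Write an LD matrix as a square labeled TSV
#'
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- data.frame(rsid = rownames(ld), unclass(ld), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
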