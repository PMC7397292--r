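# Canonical schema for variant-association tables. `position` and `eaf` are
# optional metadata; everything else is required for estimation.
.assoc_required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pvalue")
.assoc_optional <- c("position", "eaf")
.valid_alleles <- c("A", "C", "G", "T")

#' Read a variant-association table
#'
#' Reads a tab-delimited table of per-variant summary associations with one
#' trait (an exposure such as serum testosterone, or a disease outcome on the
#' log-odds scale). Column names are resolved through an optional dialect map
#' so tables exported from different GWAS pipelines can be ingested without
#' renaming on disk.
#'
#' Rows whose required fields are missing or unparsable are not read in;
#' they are recorded, with a per-row reason, in the `rejections` attribute of
#' the returned tibble so that no input variant silently disappears.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect Optional named character vector or list mapping canonical
#'   column names (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pvalue`, and optionally `position`, `eaf`) to the column names used in
#'   the file, e.g. `c(rsid = "SNP", beta = "Effect")`. Unmapped canonical
#'   names are matched case-insensitively against the file header.
#' @return A tibble with columns `rsid`, `position`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `pvalue` (and `eaf` when present), one row
#'   per accepted input row, in file order. Attribute `rejections` is a tibble
#'   with columns `row`, `rsid`, `reason` describing discarded rows.
#' @seealso [write_associations()], [harmonize()]
#' @export
read_associations <- function(path, dialect = NULL) {
  if (!is.character(path) || length(path) != 1L) {
    stop("`path` must be a single file path", call. = FALSE)
  }
  if (!file.exists(path)) {
    stop("association file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("NA", ""), strip.white = TRUE)
  lookup <- .resolve_dialect(names(raw), dialect)
  parse_associations(stats::setNames(raw[lookup], names(lookup)))
}

# Map canonical column names onto the file's header. Required columns that
# cannot be resolved raise a schema error naming the column.
.resolve_dialect <- function(header, dialect) {
  dialect <- as.list(dialect %||% list())
  bad <- setdiff(names(dialect), c(.assoc_required, .assoc_optional))
  if (length(bad)) {
    stop("unknown canonical column(s) in dialect: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  resolve_one <- function(canon) {
    wanted <- if (canon %in% names(dialect)) dialect[[canon]] else canon
    hit <- which(tolower(header) == tolower(wanted))
    if (length(hit)) header[hit[1L]] else NA_character_
  }
  lookup <- vapply(c(.assoc_required, .assoc_optional), resolve_one, character(1))
  missing_req <- .assoc_required[is.na(lookup[.assoc_required])]
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  lookup[!is.na(lookup)]
}

#' Build a validated association tibble from raw character data
#'
#' Workhorse behind [read_associations()], exposed so programmatically built
#' tables go through the same per-row validation and rejection logging.
#'
#' @param df A data frame holding (possibly character) columns named with the
#'   canonical schema (`rsid`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pvalue`, optionally `position`, `eaf`).
#' @return A validated association tibble; see [read_associations()].
#' @export
parse_associations <- function(df) {
  n <- nrow(df)
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- tibble::tibble(
    rsid = as.character(df$rsid),
    position = if ("position" %in% names(df)) {
      p <- num(df$position)
      ifelse(is.na(p), NA_integer_, as.integer(round(p)))
    } else rep(NA_integer_, n),
    effect_allele = toupper(as.character(df$effect_allele)),
    other_allele = toupper(as.character(df$other_allele)),
    beta = num(df$beta),
    se = num(df$se),
    pvalue = num(df$pvalue)
  )
  if ("eaf" %in% names(df)) out$eaf <- num(df$eaf)

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) reason[is.na(reason) & bad] <<- why
  flag(is.na(out$rsid) | !nzchar(out$rsid), "missing rsid")
  flag(is.na(out$beta), "missing or unparsable beta")
  flag(is.na(out$se), "missing or unparsable se")
  flag(out$se <= 0 & !is.na(out$se), "se must be > 0")
  flag(is.na(out$pvalue), "missing or unparsable pvalue")
  flag(!is.na(out$pvalue) & (out$pvalue <= 0 | out$pvalue > 1), "pvalue outside (0, 1]")
  flag(!(out$effect_allele %in% .valid_alleles), "invalid effect allele")
  flag(!(out$other_allele %in% .valid_alleles), "invalid other allele")
  flag(out$effect_allele == out$other_allele, "effect and other allele identical")
  if ("eaf" %in% names(out)) {
    flag(!is.na(out$eaf) & (out$eaf < 0 | out$eaf > 1), "eaf outside [0, 1]")
  }

  keep <- is.na(reason)
  rejections <- tibble::tibble(
    row = which(!keep),
    rsid = out$rsid[!keep],
    reason = reason[!keep]
  )
  out <- out[keep, , drop = FALSE]

  dup <- unique(out$rsid[duplicated(out$rsid)])
  if (length(dup)) {
    stop("duplicate rsid(s) in association table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  attr(out, "rejections") <- rejections
  out
}

#' Write a variant-association table
#'
#' Inverse of [read_associations()]: writes the canonical tab-delimited layout
#' so that a write/read round trip reproduces the table field-for-field.
#'
#' @param assoc An association tibble (see [read_associations()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(assoc, path) {
  assoc <- validate_associations(assoc)
  utils::write.table(as.data.frame(assoc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Validate an association table
#'
#' Checks the invariants every downstream operation relies on: required
#' columns present, positive standard errors, p-values in (0, 1], uppercase
#' distinct A/C/G/T alleles, and unique non-empty rsids.
#'
#' @param assoc A data frame with the canonical association columns.
#' @return The input as a tibble, invisibly usable; errors describe the first
#'   violated invariant.
#' @export
validate_associations <- function(assoc) {
  if (!is.data.frame(assoc)) stop("association table must be a data frame", call. = FALSE)
  missing_req <- setdiff(.assoc_required, names(assoc))
  if (length(missing_req)) {
    stop("missing required column(s): ", paste(missing_req, collapse = ", "),
         call. = FALSE)
  }
  assoc <- tibble::as_tibble(assoc)
  with(assoc, {
    if (any(is.na(rsid) | !nzchar(rsid))) stop("rsid must be non-empty", call. = FALSE)
    if (anyDuplicated(rsid)) {
      stop("duplicate rsid(s): ",
           paste(unique(rsid[duplicated(rsid)]), collapse = ", "), call. = FALSE)
    }
    if (any(is.na(se) | se <= 0)) stop("all se must be > 0", call. = FALSE)
    if (any(is.na(pvalue) | pvalue <= 0 | pvalue > 1)) {
      stop("all pvalue must lie in (0, 1]", call. = FALSE)
    }
    if (!all(effect_allele %in% .valid_alleles) ||
        !all(other_allele %in% .valid_alleles)) {
      stop("alleles must be single uppercase A/C/G/T", call. = FALSE)
    }
    if (any(effect_allele == other_allele)) {
      stop("effect and other allele must differ", call. = FALSE)
    }
    if (any(is.na(beta))) stop("beta must be numeric and non-missing", call. = FALSE)
  })
  assoc
}

`%||%` <- function(x, y) if (is.null(x)) y else x
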