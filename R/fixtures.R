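#' Packaged example files
#'
#' Paths to the data files shipped with the package: the serum-testosterone
#' genetic instruments at the JMJD1C (one variant) and SHBG (twenty variants)
#' loci, a derived single-variant gout outcome fixture, the reported IVW
#' reference results for seven disease outcomes, and a worked YAML analysis
#' configuration.
#'
#' The gout outcome fixture is synthetic in the sense that the original
#' outcome GWAS is not redistributable at this scale: its beta/SE were
#' back-derived by inverting the Wald ratio from the reported gout estimate,
#' so the packaged worked example reproduces the reported result exactly.
#'
#' @param name File name within `extdata`; with no argument, lists the
#'   available files.
#' @return A file path (or a character vector of file names).
#' @export
mr_example_file <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "mrpipe")))
  }
  path <- system.file("extdata", name, package = "mrpipe")
  if (!nzchar(path)) stop("no packaged file named ", name, call. = FALSE)
  path
}

#' Packaged testosterone instruments and outcome fixture
#'
#' `jmjd1c_instrument()` and `shbg_instrument()` return the exposure
#' (variant-testosterone) association tables for the two loci;
#' `gout_outcome_jmjd1c()` returns the derived gout outcome fixture matching
#' the JMJD1C variant (see [mr_example_file()] for its provenance).
#'
#' @return An association tibble (see [read_associations()]).
#' @export
jmjd1c_instrument <- function() {
  read_associations(mr_example_file("testosterone_jmjd1c.tsv"))
}

#' @rdname jmjd1c_instrument
#' @export
shbg_instrument <- function() {
  read_associations(mr_example_file("testosterone_shbg.tsv"))
}

#' @rdname jmjd1c_instrument
#' @export
gout_outcome_jmjd1c <- function() {
  read_associations(mr_example_file("gout_jmjd1c_derived.tsv"))
}

#' Reported reference IVW results
#'
#' The published per-outcome IVW results (odds ratio, log-odds estimate, SE,
#' displayed p-value, and — where reported — 95% CI endpoints and MR-Egger
#' intercept) for the seven disease outcomes, one table per locus. Used as
#' reference values in consistency checks.
#'
#' @param locus `"jmjd1c"` or `"shbg"`.
#' @return A tibble, one row per outcome.
#' @export
reported_estimates <- function(locus = c("jmjd1c", "shbg")) {
  locus <- match.arg(locus)
  path <- mr_example_file(sprintf("reported_ivw_%s.tsv", locus))
  tibble::as_tibble(utils::read.delim(
    path, sep = "\t", check.names = FALSE,
    colClasses = c(pvalue_display = "character")))
}
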