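#' Build an analysis configuration
#'
#' @param loci List of locus specs: each a list with `label`, `exposure`
#'   (TSV path), `mode` (`"single_variant"` or `"multi_variant"`), and for
#'   multi-variant loci optionally `ld` (LD TSV path; when present the
#'   candidates are pruned) and `r2_threshold` (default 0.40).
#' @param outcomes List of outcome specs: each a list with `label` and `path`.
#' @param methods Methods to run where the variant count permits: subset of
#'   `"ivw"`, `"weighted_median"`, `"egger"`.
#' @param effects_model IVW effects model, `"fixed"` or `"random"`.
#' @param delta_order Ratio SE order for single-variant instruments.
#' @param palindromic_policy Passed to [harmonize()].
#' @param n_boot Bootstrap replicates for the weighted median.
#' @param seed Integer seed; required whenever `weighted_median` is requested.
#' @param output Optional list with paths `report` and/or `log`; written as
#'   TSV when present.
#' @return A validated list of class `mr_analysis_config`.
#' @export
analysis_config <- function(loci, outcomes,
                            methods = c("ivw", "weighted_median", "egger"),
                            effects_model = c("fixed", "random"),
                            delta_order = c("first", "second"),
                            palindromic_policy = c("drop", "keep"),
                            n_boot = 1000, seed = NULL, output = list()) {
  effects_model <- match.arg(effects_model)
  delta_order <- match.arg(delta_order)
  palindromic_policy <- match.arg(palindromic_policy)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(loci) == 0L) stop("config needs at least one locus", call. = FALSE)
  if (length(outcomes) == 0L) stop("config needs at least one outcome", call. = FALSE)
  for (lc in loci) {
    if (is.null(lc$label) || is.null(lc$exposure)) {
      stop("each locus needs `label` and `exposure`", call. = FALSE)
    }
    if (!is.null(lc$mode) &&
        !lc$mode %in% c("single_variant", "multi_variant")) {
      stop("locus mode must be single_variant or multi_variant", call. = FALSE)
    }
  }
  for (oc in outcomes) {
    if (is.null(oc$label) || is.null(oc$path)) {
      stop("each outcome needs `label` and `path`", call. = FALSE)
    }
  }
  if ("weighted_median" %in% methods && is.null(seed)) {
    stop("`seed` is required when the weighted median is requested", call. = FALSE)
  }
  structure(
    list(loci = loci, outcomes = outcomes, methods = methods,
         effects_model = effects_model, delta_order = delta_order,
         palindromic_policy = palindromic_policy,
         n_boot = n_boot, seed = if (is.null(seed)) NULL else as.integer(seed),
         output = output),
    class = "mr_analysis_config"
  )
}

#' Read an analysis configuration from a YAML file
#'
#' The YAML mirrors the arguments of [analysis_config()]; relative paths are
#' resolved against the config file's directory.
#'
#' @param path Path to a YAML file.
#' @return An `mr_analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) {
    if (is.null(p)) NULL
    else if (grepl("^(/|[A-Za-z]:)", p)) p
    else file.path(base, p)
  }
  y$loci <- lapply(y$loci, function(lc) {
    lc$exposure <- rel(lc$exposure)
    lc$ld <- rel(lc$ld)
    lc
  })
  y$outcomes <- lapply(y$outcomes, function(oc) {
    oc$path <- rel(oc$path)
    oc
  })
  do.call(analysis_config, c(
    y[intersect(names(y), c("loci", "outcomes", "methods", "effects_model",
                            "delta_order", "palindromic_policy", "n_boot",
                            "seed"))],
    list(output = y$output %||% list())
  ))
}

#' Run the full two-sample MR analysis
#'
#' For every locus-by-outcome pair: harmonize the exposure instrument with
#' the outcome summary statistics (after optional stepwise LD pruning of a
#' multi-variant locus), estimate the causal effect by IVW — which is exactly
#' the Wald ratio when a single variant survives — and run the requested
#' sensitivity analyses where the surviving variant count permits (the
#' weighted median and MR-Egger need at least 3 variants and are skipped,
#' with a logged note, otherwise). An outcome whose harmonization leaves no
#' variants is recorded as failed and the run continues.
#'
#' No multiple-testing correction is applied; significance is flagged at raw
#' two-sided p < 0.05, and the run log records how many tests were run.
#'
#' @param config An `mr_analysis_config`, or a path to a YAML file for
#'   [read_analysis_config()].
#' @param quiet Suppress progress messages (default `FALSE`).
#' @return The report tibble (one row per locus/outcome/method; see
#'   [to_report_row()]), with attribute `run_log`: a tibble recording, per
#'   locus and outcome, input/pruned/harmonized variant counts, drop reasons,
#'   methods run or skipped, and settings. Output files are written when
#'   `config$output` names them.
#' @export
run_analysis <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "mr_analysis_config"))
  say <- function(...) if (!quiet) message(format(Sys.time(), "%H:%M:%S "), ...)

  rows <- list()
  log <- list()
  for (lc in config$loci) {
    exposure <- read_associations(lc$exposure)
    n_input <- nrow(exposure)
    prune_note <- "not pruned"
    if (identical(lc$mode, "multi_variant") && !is.null(lc$ld)) {
      ld <- read_ld_matrix(lc$ld)
      sel <- stepwise_select(exposure, ld, lc$r2_threshold %||% 0.40)
      exposure <- exposure[exposure$rsid %in% sel$selected, , drop = FALSE]
      prune_note <- sprintf("pruned %d -> %d at r2 > %g", n_input,
                            nrow(exposure), sel$r2_threshold)
    }
    say(sprintf("locus %s: %d instrument variant(s) (%s)", lc$label,
                nrow(exposure), prune_note))

    for (oc in config$outcomes) {
      outcome <- read_associations(oc$path)
      entry <- list(locus = lc$label, outcome = oc$label,
                    n_input = n_input, n_instrument = nrow(exposure),
                    prune = prune_note)
      h <- tryCatch(
        harmonize(exposure, outcome, config$palindromic_policy),
        error = function(e) e
      )
      if (inherits(h, "error")) {
        say(sprintf("  %s: FAILED (%s)", oc$label, conditionMessage(h)))
        entry$n_harmonized <- 0L
        entry$status <- paste("failed:", conditionMessage(h))
        entry$drops <- ""
        entry$methods_run <- ""
        entry$methods_skipped <- paste(config$methods, collapse = ",")
        log[[length(log) + 1L]] <- entry
        next
      }
      dl <- attr(h, "drop_log")
      entry$n_harmonized <- nrow(h)
      entry$status <- "ok"
      entry$drops <- if (nrow(dl)) {
        paste(sprintf("%s:%s", dl$rsid, dl$reason), collapse = ";")
      } else ""

      J <- nrow(h)
      run <- character(0)
      skipped <- character(0)
      if ("ivw" %in% config$methods) {
        est <- if (J == 1L) {
          ratio <- ratio_estimate(h$beta_x, h$se_x, h$beta_y, h$se_y,
                                  config$delta_order)
          ratio$method <- "ivw"  # single-variant IVW is the Wald ratio
          ratio
        } else {
          ivw_estimate(h, config$effects_model)
        }
        rows[[length(rows) + 1L]] <- to_report_row(est, oc$label, lc$label)
        run <- c(run, "ivw")
      }
      if ("weighted_median" %in% config$methods) {
        if (J >= 3L) {
          est <- weighted_median(h, config$n_boot, config$seed)
          rows[[length(rows) + 1L]] <- to_report_row(est, oc$label, lc$label)
          run <- c(run, "weighted_median")
        } else {
          say(sprintf("  %s: weighted median skipped (%d variant(s))",
                      oc$label, J))
          skipped <- c(skipped, "weighted_median")
        }
      }
      if ("egger" %in% config$methods) {
        if (J >= 3L) {
          est <- egger_regression(h)
          rows[[length(rows) + 1L]] <- to_report_row(est, oc$label, lc$label)
          run <- c(run, "egger")
        } else {
          say(sprintf("  %s: MR-Egger skipped (%d variant(s))", oc$label, J))
          skipped <- c(skipped, "egger")
        }
      }
      entry$methods_run <- paste(run, collapse = ",")
      entry$methods_skipped <- paste(skipped, collapse = ",")
      log[[length(log) + 1L]] <- entry
      say(sprintf("  %s: %d variant(s), methods: %s", oc$label, J,
                  entry$methods_run))
    }
  }

  report <- do.call(rbind, rows)
  run_log <- do.call(rbind, lapply(log, tibble::as_tibble))
  run_log$n_tests_total <- if (is.null(report)) 0L else nrow(report)
  attr(report, "run_log") <- run_log

  if (!is.null(config$output$report)) {
    utils::write.table(as.data.frame(report), config$output$report,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    say("report written to ", config$output$report)
  }
  if (!is.null(config$output$log)) {
    utils::write.table(as.data.frame(run_log), config$output$log,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report
}
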