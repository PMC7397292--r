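Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with summary-level
    GWAS data: reading and harmonizing variant-association tables, greedy
    p-value-ranked LD pruning for instrument construction, causal estimation
    by the Wald ratio and inverse-variance-weighted methods (with an optional
    correlation-aware generalized-least-squares variant), weighted-median and
    MR-Egger sensitivity analyses, odds-scale reporting, and a seeded
    generator of synthetic two-sample summary statistics with configurable
    pleiotropy for validation. Ships the serum-testosterone instruments at
    the JMJD1C and SHBG loci together with reported reference results as
    packaged fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
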