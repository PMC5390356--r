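Package: progsig
Title: Prognostic Gene Signature Discovery for Tumor Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering prognostic gene
    signatures in tumor expression cohorts with right-censored survival:
    probe-to-gene collapsing and low-information filtering, subsampled
    consensus clustering of samples, empirical-Bayes moderated t
    differential expression, an iterative cluster/differential stabilization
    loop, Kaplan-Meier mean-split screening of prognostic seed genes,
    fold-change threshold optimization of the key gene set, hypergeometric
    over-representation analysis, and multivariate survival validation with
    Cox regression and time-dependent ROC. Includes a synthetic cohort
    generator with planted subtype and hazard structure for calibration and
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
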