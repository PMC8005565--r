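Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Instrument selection, LD clumping, allele harmonization and the
    full family of summary-data Mendelian randomization estimators (Wald
    ratio, fixed- and random-effects inverse-variance weighted, simple and
    weighted median with penalized weights, penalized and robust IVW,
    MR-Egger regression), together with Cochran's Q heterogeneity testing,
    leave-one-out sensitivity analysis, funnel- and scatter-plot data
    export, and a synthetic two-sample summary-statistic generator with
    known causal and pleiotropic structure for estimator validation. Ships
    a nine-variant hypothyroidism/non-alcoholic fatty liver disease
    instrument set as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
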