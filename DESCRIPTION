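Package: mrscreen
Title: Triangulated Mendelian Randomization Screening of Metabolite Mediators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for triangulating adiposity-metabolite-cancer relationships
    with two-sample Mendelian randomization (MR) and parallel observational
    analyses. Implements the Wald ratio, multiplicative random-effects
    inverse-variance weighted (IVW-MRE), MR-Egger, weighted-median and
    weighted-mode estimators; multivariable MR with conditional F-statistics
    and the adapted heterogeneity statistic Q_A; GWAS summary-statistic
    reading, greedy LD clumping and effect-allele harmonization; inverse
    rank-normal transformation and covariate-adjusted cohort regressions; a
    four-part sequential mediation screen with auditable filter decisions;
    and a phenome-catalogue enrichment scan against an iterated
    random-metabolite null. A synthetic-study generator with known mediation
    ground truth supports calibration and end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
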