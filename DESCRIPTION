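Package: gxecross
Title: Gene-Environment Interaction Analysis with Re-Parameterized
    Crossover Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing and characterising gene-environment (GxE)
    interactions on quantitative traits with a small SNP panel: variant-level
    quality control (Hardy-Weinberg equilibrium, allele frequency, call rate),
    risk-allele dosage coding and cumulative genetic scores, a
    gene-environment correlation screen, exploratory moderated-regression
    interaction tests with nested-F comparisons and Bonferroni control, and
    confirmatory re-parameterized crossover regression that arbitrates
    between strong and weak forms of the differential-susceptibility and
    diathesis-stress models via profiled nonlinear least squares, Wald
    intervals for the crossover point, and AIC/BIC model comparison. A
    synthetic-cohort generator reproduces the statistical structure the
    analysis assumes so that every stage can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
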