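Package: gwasfdr
Title: Multiple-Testing Procedures and Empirical FDR Evaluation for GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing multiple-testing strategies in common-variant
    genome-wide association studies (GWAS): fixed P-value thresholds and
    Bonferroni control of the family-wise error rate, locus-adapted
    Benjamini-Hochberg and Benjamini-Yekutieli step-up control of the false
    discovery rate, and Bayesian FDR control through Wakefield approximate
    Bayes factors and the Bayesian false discovery probability, in both
    univariate and multivariate (metaMANOVA) settings.  Includes summary-
    statistics input/output and harmonization, greedy P-value-ordered LD
    clumping of variants into loci, empirical-FDR evaluation of a test study
    against a larger truth study, a block-LD genotype and quantitative-trait
    simulator with known causal architecture, and a replicate study driver
    that aggregates true and false positive counts with Monte Carlo standard
    errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
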