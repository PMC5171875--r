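Package: mrwald
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Artifact", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization using published
    GWAS summary statistics: reading and validating per-SNP association
    tables, genome-wide-significance filtering, greedy LD pruning,
    effect-allele harmonization, per-SNP Wald ratios with Fieller's-theorem
    confidence limits, fixed-effect inverse-variance-weighted pooling,
    MR-Egger regression with its directional-pleiotropy intercept test, the
    weighted median estimator with parametric-bootstrap standard errors, a
    sensitivity battery (pleiotropy exclusion and a weight-share rule
    choosing between weighted median and MR-Egger), a summary-level
    simulator with known ground truth, and a configuration-driven pipeline
    runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
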