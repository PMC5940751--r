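Package: crosstrait
Title: Two-Sample Mendelian Randomization and Cross-Trait Genetic
    Architecture from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing shared genetic aetiology between two
    complex traits from genome-wide association summary statistics:
    reading and harmonizing per-allele effect estimates across studies,
    selecting genetic instruments at genome-wide significance or by false
    discovery rate, Wald-ratio and inverse-variance-weighted fixed-effect
    Mendelian randomization with Cochran Q heterogeneity, leave-one-out
    outlier diagnosis and Egger regression sensitivity analysis,
    cross-trait LD score regression with block-jackknife uncertainty, and
    a four-model Bayesian scan distinguishing shared from distinct causal
    variants within a genomic region. Includes seeded simulators of
    paired GWAS summary statistics, haplotype panels, genome-wide z-score
    pairs and regional signals with serialized ground truth, so that
    every estimator is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
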