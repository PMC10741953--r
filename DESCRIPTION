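Package: imprintscan
Title: Control-Panel Differential Methylation Analysis for Imprinted Regions
Version: 0.1.0
Authors@R: person("Imprintscan", "Developers", role = c("aut", "cre"),
    email = "imprintscan@example.org")
Description: A pipeline for calling differential DNA methylation on
    methylation-array beta values against a panel of control samples.
    Supports per-CpG, 500 bp bin and region-level outlier calling using an
    M-value statistic (|dM| > k*SD of controls) combined with a beta-scale
    effect-size threshold (|dbeta| > 0.2), detection of clusters of
    contiguous differentially methylated bins, analysis of imprinted
    differentially methylated regions (iDMRs) including methylation-recovery
    classification in mutation-corrected clones, genomic-element annotation
    with a permutation (shuffle) overlap test, ChIP-seq IP/input fold-change
    integration with paired Wilcoxon statistics, and a truth-annotated
    synthetic data generator emulating a control/patient/corrected iPSC
    study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
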