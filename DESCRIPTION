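Package: cphcap
Title: Non-CpG Methylation Analysis of Pluripotent Stem Cell Differentiation Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Discovery and replication analysis of non-CpG (CpH) DNA
    methylation measured on Illumina 450K-style arrays as a biomarker of
    endodermal differentiation capacity in pluripotent stem cell lines.
    Provides a seeded synthetic cohort generator with 450K-like structure,
    sample- and probe-level quality control (bisulfite conversion efficiency
    from control-probe intensities, detection-p filtering, genotype-probe
    replicate outlier flagging, SVD confounder scan), empirical-Bayes
    moderated t-tests on M-values with Benjamini-Hochberg calling of
    methylation variable positions, label-permutation and Monte Carlo
    CpG-subsampling nulls for the group mean difference, a nine-probe
    confidence-interval-midpoint threshold classifier with replication
    prediction, hierarchical clustering of cell lines, and promoter-level
    comparison against a published Reference Corridor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    IRanges,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
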