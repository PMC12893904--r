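Package: immunokit
Title: Spatial, Repertoire and Calibration Analytics for Age-Dependent
    Immune Signalling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how immune cell organisation and function change
    with age and treatment. Implements a radius-based spatial interaction
    Z statistic with Pearson age-trend testing, permutation-scored
    ligand-receptor interactions with Spearman/Bonferroni trend calls,
    graph heat-kernel smoothing over spatial Delaunay triangulations for
    tissue region identification, hierarchical marker-based cell typing
    with quality-control filtering, TCR clonotype and tetramer-gating
    repertoire metrics (Shannon diversity, CLR normalisation,
    equal-depth downsampling), an inverse-calibrated "immunological
    vaccination response age" from quadratic standard curves, and small
    assay summaries (TREC -dCt, trapezoid AUC, fold change). Ships a
    synthetic-data generator that emulates the statistical structure of
    each input so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr,
    withr
Suggests:
    expm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
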