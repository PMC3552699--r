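Package: pathclust
Title: Pathway-Assisted Clustering of Breast Cancer Subtypes from Plasma Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative pathway-assisted clustering of breast cancer subtypes
    from label-free plasma proteomics. Implements a variance-adaptive
    permutation test (an F test chooses the pooled-variance or Welch t
    statistic at every resample), Benjamini-Hochberg adjustment and
    Storey-Tibshirani q-values; pathway-protein matrices at three q-value
    cutoffs merged by elementwise maximum; four subtype distance metrics
    (protein-intensity effects, q-value profiles, pathway profiles, and a
    distance score on pathway-protein matrices); hierarchical clustering with
    Newick export; nearest-neighbor subtype prediction with accuracy
    evaluation; and Jaccard pathway association networks. Includes a synthetic
    cohort generator with planted differential proteins and pathway structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
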