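Package: fdgmuscle
Title: Quantification of [18F]-FDG Muscle Uptake on PET with Fixed and
    Hotspot Volumes of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying skeletal-muscle glucose uptake on
    reconstructed [18F]-FDG PET volumes. Implements body-weight SUV
    conversion, SUVpeak extraction from spherical volumes of interest,
    two VOI-placement procedures (fixed anatomical position along the
    bone axis and hotspot position with consecutive-slice confirmation),
    an automated analog of visual positivity and homogeneous versus
    heterogeneous pattern scoring against a mediastinal blood-pool
    reference, and the accompanying statistical battery (paired t,
    Pearson/Spearman correlation, Bland-Altman agreement, a
    Shapiro-Wilk/F-test normality gate, Kruskal-Wallis with Dunn's
    post-hoc). A digital whole-body phantom generator with known
    per-muscle ground truth drives verification of every stage without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
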