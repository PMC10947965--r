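Package: uwmc
Title: Unhealthy White Matter Connectivity from Tractograms and Lesion Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies unhealthy white matter connectivity (UWMC), the
    proportion of tractography streamlines between each pair of brain regions
    that pass through white matter hyperintensity (WMH) lesions. Provides
    fuzzy c-means WMH segmentation of reference-normalized FLAIR images,
    streamline-lesion intersection and end-to-end pair counting on NIfTI
    parcellations with TCK/TRK tractograms, lobar and global aggregation,
    ICV-normalized lobar lesion volumes, and a cohort-level statistical
    pipeline (resampled elastic-net stability selection with forced
    covariates, Huber M robust regression, Benjamini-Hochberg false discovery
    rate control, Spearman lobar validation, and descriptive group
    comparisons). Includes a synthetic phantom and cohort generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    MASS,
    glmnet,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
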