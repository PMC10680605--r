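Package: sepaldyn
Title: Quantitative Morphodynamics of Growing Sepals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying tissue morphodynamics from time-lapse
    cell-resolution imaging of plant organs: lineage tracking algebra over
    parent-label maps, per-cell and per-lineage areal growth, principal
    directions of growth from deformation tensors, proximal-distal axis
    fields and growth-direction anisotropy, organ contour shape-robustness
    statistics, and distribution-comparison statistics (1-d Wasserstein
    distances, principal coordinate analysis, Kendall rank correlation,
    one-way ANOVA with Tukey letter groups). Includes a synthetic
    growing-tissue simulator implementing basipetal banded growth with
    controllable spatiotemporal growth noise, division-rate modulation and
    non-dividing giant cells, so the whole pipeline runs without microscopy
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    igraph,
    generics,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    png,
    jsonlite,
    withr
Config/testthat/edition: 3
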