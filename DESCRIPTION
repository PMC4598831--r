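Package: inputmap
Title: Whole-Brain Quantification of Monosynaptic Inputs from Light-Sheet Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for whole-brain mapping of rabies-labeled
    monosynaptic inputs in cleared-tissue light-sheet volumes. Detects cell
    bodies by random-forest pixel classification and 3D connected-component
    centroid extraction with diameter, slice-consecutiveness and circularity
    filters; registers brains to a common 20-micron reference space by
    mutual-information affine alignment; assigns centroids to atlas regions
    with starter-region exclusion and computes per-brain input-percentage
    profiles; compares conditions by one-way ANOVA with Holm-Sidak correction,
    Pearson correlation matrices and average-linkage clustering; and maps
    topography by section-wise centers of mass and kernel-density "ventral
    patch" segmentation. Ships a synthetic-data generator (toy atlases,
    simulated volumes with planted cells, multi-brain multi-condition centroid
    cohorts) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    Rcpp,
    RNifti,
    stats,
    tibble,
    tidyr,
    tiff,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
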