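Package: g4quant
Title: Quantification of G-Quadruplex and DNA-Damage Foci with
    Dose-Response and Synergy Analytics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Per-cell quantification of punctate fluorescent foci in
    3D microscopy z-stacks (G-quadruplex probe and gamma-H2AX staining),
    with nucleus segmentation from DAPI, voxel-size filtering, nucleolus
    exclusion and condition-level fold-change summaries; four-parameter
    logistic dose-response fitting (IC50 and apparent KD), FRET-melting
    half-transition temperatures and their ligand-induced shifts; and
    Bliss-independence synergy scoring of drug-pair viability matrices.
    Includes synthetic-data generators with exact ground truth so every
    stage of the pipeline is testable without raw images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
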