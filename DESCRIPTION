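Package: ectopiscan
Title: Scoring and Quantification of CENP-A Mislocalization Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for image-based RNAi screens of
    centromeric histone (CENP-A) mislocalization and the follow-up assays
    around them. Provides plate-level quality control (Z'-factor), negative
    control normalization, siRNA seed-based off-target correction of Z-scores
    and gene-level hit calling for high-content screens; segmentation-based
    quantification of nuclear, cell-cycle-resolved (EdU/DAPI gated) and
    metaphase-spread centromeric versus noncentromeric fluorescence signals;
    and label-free IP-MS differential interactome statistics with downshifted
    missing-value imputation, bait normalization and an s0-moderated
    permutation-FDR two-sample test. Synthetic-data generators with known
    ground truth emulate each input modality for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
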