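Package: tissuemil
Title: Quality-Weighted Tissue-Based Multiple Instance Learning for Whole-Slide Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for slide-level prediction from segmented tissue compartments
    of renal biopsy images. Implements uncertainty-penalised fusion of
    segmentation-ensemble probability maps, max-flow/min-cut tissue instance
    extraction, per-instance segmentation quality weights, handcrafted
    morphology/colour/texture/nuclei feature extraction, a gated soft-attention
    multi-instance classifier with optional quality-weighted attention,
    tissue-count-weighted ROC/PR evaluation with donor-grouped cross-validation,
    and attention-confined visualisation with occlusion saliency. A synthetic
    slide and bag generator with analytic ground truth supports end-to-end
    testing without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    EBImage,
    stats,
    grDevices,
    jsonlite,
    yaml,
    png,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
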