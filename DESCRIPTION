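Package: BrainTumorKFCM
Title: Hybrid Clustering and Morphological Segmentation of Brain Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of hyperintense tumor and edema regions in 2D
    FLAIR-like brain MR slices by a hybrid pipeline: adaptive Wiener
    denoising and morphological skull stripping, Gaussian-kernel fuzzy
    C-means clustering with deterministic K-means++ centroid
    initialization (K++GKFCM), threshold-based tumor extraction, and
    hole-filling/median-filter postprocessing. Includes classical K-means
    and fuzzy C-means baselines, pixel-overlap evaluation metrics in both
    the printed and the standard formulations, and a ground-truthed
    synthetic brain-phantom generator for end-to-end testing and
    noise-robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    png,
    tiff,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: ImageSegmentation, Clustering, Preprocessing
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
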