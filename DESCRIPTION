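Package: slicecov
Title: Tumor Coverage Estimation from Single CT Slices After Thermal Ablation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the percentage of a liver tumor covered by a thermal
    ablation zone from a single axial CT slice per lesion, avoiding full 3D
    segmentation and registration at inference time. Computes volumetric
    ground-truth coverage from paired binary masks, extracts and standardizes
    isocenter slices, builds noise-augmented image-pair cohorts with
    leakage-safe case-level splits, derives deep-feature difference vectors
    (Siamese-style differencing over a VGG16-shaped or random-convolution
    backbone), and trains random-forest and neural-network heads to classify
    or regress coverage. Ships a synthetic ellipsoid phantom generator with
    controllable overlap so the whole pipeline is testable without patient
    data, plus one-vs-rest ROC and regression error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    ranger,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
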