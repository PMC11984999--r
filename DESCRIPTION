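Package: fedmammo
Title: Mammography Harmonization and Federated Learning Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for DICOM-driven mammogram harmonization
    and in-process federated training of BIRADS classifiers. Provides
    metadata-driven pre-processing (rescale, photometric inversion,
    laterality alignment, pixel-spacing-aware resizing), a breast-area
    detection pipeline that bootstraps masks with K-means clustering,
    augments them with fake printed labels and trains a small UNet to
    remove labels and artifacts, patient-wise cohort splitting with
    leakage control, a lightweight convolutional BIRADS classifier, and a
    deterministic FedAvg simulator for studying non-IID hospital
    heterogeneity. A synthetic phantom generator with known ground-truth
    masks makes every stage testable without access to clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    withr,
    grDevices,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
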