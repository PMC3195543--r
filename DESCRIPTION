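Package: cariomics
Title: Salivary Proteomic and Oral Microbial Biomarker Discovery for Dental Caries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for case/control biomarker discovery from
    SELDI-TOF mass-spectrometry salivary proteome profiles and checkerboard
    DNA-DNA hybridization oral microbial arrays. Implements spectral
    preprocessing (cube-root variance stabilization, moving-window baseline
    subtraction, total-ion-current normalization, Gaussian smoothing, and
    peak-based dynamic-programming alignment), two-stage peak calling on the
    cohort mean profile, universal-probe abundance normalization, Wilcoxon
    rank-sum feature screening, linear SVM and random-forest classification
    under repeated 70:30 random-subsampling validation with ROC/AUC, and
    column-wise fusion of matched microbial and proteomic feature blocks.
    A synthetic cohort generator with planted ground truth makes every stage
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
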