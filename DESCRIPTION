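Package: petrad
Title: Amino-Acid PET Radiomics for Recurrent Brain Tumor versus Radiation Necrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end methionine-PET radiomics pipeline for discriminating
    recurrent brain tumor from radiation necrosis. Provides synthetic brain-PET
    phantom cohorts, cortex-referenced SUV threshold segmentation with exclusion
    rules, fixed-bin gray-level discretization and a 42-feature panel of
    conventional, histogram, shape, co-occurrence (GLCM), run-length (GLRLM),
    neighborhood-difference (NGLDM) and size-zone (GLZLM) features, SMOTE-balanced
    random-forest classification with repeated stratified 10-fold cross-validation
    and mean-decrease-Gini importance, and diagnostic evaluation (confusion
    metrics, ROC/AUC with Youden cutoff, Mann-Whitney and Spearman statistics)
    benchmarked against tumor-to-normal-cortex ratio evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
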