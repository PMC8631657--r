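Package: breathfaims
Title: Breath Volatolomics Analysis for TD-GC-FAIMS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for breath volatolomic profiles measured by
    thermal desorption gas chromatography coupled to field asymmetric ion
    mobility spectrometry (TD-GC-FAIMS). Covers simulation of raw
    dispersion-field ion-intensity matrices with known ground truth,
    a documented plain-text on-disk run format, preprocessing to
    blank-subtracted separation chromatograms, detection and quantification
    of intensity-thresholded molecular features, ROC-based feature selection,
    a logistic-regression molecular-feature score, supervised disease-stage
    classifiers (random under-sampling boosted trees, subspace k-nearest
    neighbours, Gaussian naive Bayes, Gaussian-kernel support vector
    machines) with tandem cascade staging, and replicate-variability
    quantification via fixed-length embeddings and mean pairwise Euclidean
    distances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    e1071,
    rpart,
    pracma,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
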