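Package: tfoccupancy
Title: Transcription Factor Occupancy Modelling and Chromatin
    Accessibility Dependence Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts ChIP-seq-like transcription factor (TF) binding
    profiles from DNA sequence, a JASPAR binding motif, TF abundance and a
    chromatin accessibility track using a statistical-thermodynamics
    occupancy model. The two free parameters (number of bound molecules N
    and specificity factor lambda) are trained on ChIP-seq data by
    grid-search over genomic bins, predictions are validated by ROC AUC,
    and each TF's dependence on DNA accessibility is classified (AIF, ADF,
    IDF and partial classes) by re-fitting the model across quantile
    density accessibility (QDA) thresholds. Includes a seeded synthetic
    data generator emulating ChIP and accessibility experiments so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
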