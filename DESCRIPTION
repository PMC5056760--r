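Package: m6Ascan
Title: Prediction of N6-Methyladenosine Sites in Mammalian mRNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans mRNA and full-transcript sequences for DRACH-motif
    adenosines and classifies each candidate as methylated or not with an
    RBF-kernel support vector machine. Candidates are encoded with four
    feature families: positional one-hot encoding of the flanking window,
    k-mer (k = 3, 4) frequency spectra over a 101-nt window, relative
    position along the transcript, and a shuffle-based Z-score of local
    secondary-structure minimum free energy. Includes specificity-calibrated
    stringency thresholds, cross-validation and unbalanced independent-test
    evaluation (ROC/AUROC, PR/AUPR, MCC), single-nucleotide site assignment
    within MeRIP-seq peak windows, and a synthetic-data generator with
    plantable methylation signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
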