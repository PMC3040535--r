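Package: phospred
Title: Phosphorylation-Site Prediction with Bagged Classifiers and
    Specificity Calibration
Version: 0.1.0
Authors@R:
    person("phospred", "developers", email = "phospred@example.org",
           role = c("aut", "cre"))
Description: An open framework for machine-learning-based prediction of
    protein phosphorylation sites. Candidate serine/threonine/tyrosine
    residues are encoded as fixed-width sequence windows and scored with
    three feature sets: k-nearest-neighbour similarity scores against a
    labelled reference set (BLOSUM62 window similarity), intrinsic-disorder
    scores, and amino-acid frequencies. Highly unbalanced site data are
    handled by a bootstrap-aggregating ensemble of binary classifiers
    (linear SVM or adaptive boosting base learners), and decision
    thresholds are calibrated against held-out negative scores so that
    prediction stringency can be adjusted continuously as an estimated
    specificity. Includes readers and writers for FASTA, a PTM-annotation
    XML dialect, UniProt XML conversion and Phospho.ELM-style reports,
    utilities for merging annotations, building non-redundant datasets and
    site statistics, a synthetic-proteome generator with planted motif and
    disorder signal for end-to-end testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    utils,
    withr,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
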