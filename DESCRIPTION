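Package: tcrmil
Title: Multiple Instance Learning Classification of TCR CDR3 Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies T cell receptor beta-chain (TCRB) CDR3 repertoires as
    cancer-associated or healthy from short biophysicochemical sequence motifs.
    CDR3 amino-acid sequences are trimmed, cut into contiguous or gapped 3- and
    4-residue motifs, encoded with Atchley factors plus a template-weighted
    relative-abundance term, and scored with a logistic model whose per-motif
    probabilities are aggregated by the maximum, the standard multiple instance
    learning assumption. Parameters are fitted by full-batch Adam over many
    random restarts. The package includes patient-hold-out cross-validation
    with shared initial weights, early stopping on the held-out loss curve,
    a label-permutation null, a model-configuration grid runner, refit-and-test
    scoring with ROC, a synthetic-repertoire generator with planted motifs for
    download-free testing, and readers for AIRR Rearrangement and Adaptive
    immunoSEQ tab-separated exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
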