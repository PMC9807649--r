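Package: octhmm
Title: Hidden Markov Model Identification of Cystic Retinal OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cyst-containing B-scans in ordered retinal optical
    coherence tomography (OCT) volumes. Per-scan feature vectors (histogram of
    oriented gradients, Harris, minimum-eigenvalue, FAST and determinant-of-
    Hessian keypoint detectors, or a pluggable deep-embedding backend) are
    ranked by linear-SVM / k-nearest-neighbour test accuracy, then used as
    observations of a two-state ergodic hidden Markov model whose hidden state
    is the cystic status of each scan. The model is trained by supervised
    counting and averaging of per-patient transition, emission and initial-state
    estimates and decoded by the Viterbi algorithm over each patient's ordered
    scan sequence. Includes a synthetic phantom and sequence generator, ROC/AUC
    evaluation and DeLong comparison of correlated ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    jsonlite,
    pROC,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
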