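Package: cmiphmm
Title: Interface Residue Prediction with Interaction-Profile HMMs and
    Contact-Matrix Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interacting residues for
    domain-domain interaction (DDI) families. Builds interaction-profile
    hidden Markov models (ipHMMs) whose match states are split into
    interacting and non-interacting flavours, decodes member sequences by
    posterior decoding, extracts Fisher-score features, predicts the
    residue-residue contact matrix between the two domains with an
    RBF-kernel support vector machine on Fisher plus windowed AAindex
    physicochemical features, and feeds each residue's predicted
    contact-matrix row or column together with its ipHMM site score into an
    L2-penalised logistic-regression site classifier. Includes a synthetic
    DDI-family generator with known ground truth, a leave-one-out
    cross-validation harness, the usual binary-classification metric suite
    (accuracy, precision, recall, F1, MCC) and paired t-tests between
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    seqinr,
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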