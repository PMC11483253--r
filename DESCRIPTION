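Package: tedi
Title: Temporal Distribution Matching for Text Encoder Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains small masked-language-model text encoders whose document
    embeddings are statistically indistinguishable across time periods. An
    adversarial linear discriminator tries to tell old from new documents from
    their sentence-embedding matrices while the encoder is simultaneously
    trained on masked-token prediction and anchored, via a Frobenius-distance
    penalty, to a frozen reference encoder. Ships a synthetic temporal-drift
    corpus generator with planted concept pairs, synthetic patient-record
    generation, intrinsic evaluations (held-out masked-language-model loss,
    temporal probe, future semantic-relatedness ranking), frozen-encoder
    downstream prediction heads with group-wise evaluation, and the paired
    statistics used to compare models (AUC with DeLong's test, Diebold-Mariano
    with the mean-absolute-deviation criterion, bootstrap confidence
    intervals).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
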