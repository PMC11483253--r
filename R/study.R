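# Reproducible synthetic studies: the distribution-matching experiment
# (baseline vs TeDi vs no-anchor ablation vs new-period reference, over
# several seeds) and the downstream patient-prediction experiment. These
# drivers define the package's canonical small-scale study conditions and
# are used by the acceptance machinery; every sub-seed is derived from the
# caller's seed.

study_seed <- function(seed, k) (abs(seed) %% 1000000L) * 1000L + k

#' Run the synthetic distribution-matching study
#'
#' For each seed: generates a drifted corpus with planted concept pairs,
#' trains an MLM-only baseline (which doubles as the frozen anchor), a
#' distribution-matched encoder, optionally its no-anchor ablation, and a
#' new-period-only reference model; then measures temporal-probe
#' accuracies, held-out MLM losses under a shared masking seed, and
#' mention-averaged future-relatedness correlations against the reference.
#'
#' @param seeds Integer vector of study seeds (one replicate each).
#' @param vocab_size,n_docs_old,n_docs_new,delta Corpus conditions.
#' @param n_pairs Planted concept pairs.
#' @param hidden,layers,n_heads,ff_size Encoder architecture.
#' @param epochs Training epochs for every model.
#' @param lambda_adv,lambda_anchor Loss weights of the matched encoder.
#' @param lr,lr_disc Generator and discriminator Adam rates.
#' @param batch_size Documents per batch.
#' @param train_fraction Train share of the corpus split.
#' @param include_ablation Also train the `lambda_anchor = 0` ablation.
#' @param progress Print per-seed progress lines.
#' @return A data frame with one row per seed: probe accuracies, held-out
#'   MLM losses and their ratio, and future-relatedness correlations.
#' @export
tedi_synthetic_study <- function(seeds = 1:3,
                                 vocab_size = 500,
                                 n_docs_old = 1000, n_docs_new = 1000,
                                 delta = 0.8, n_pairs = 20,
                                 hidden = 64, layers = 2, n_heads = 2,
                                 ff_size = 2 * hidden,
                                 epochs = 5,
                                 lambda_adv = 0.3, lambda_anchor = 0.3,
                                 lr = 1e-3, lr_disc = 1e-2,
                                 batch_size = 16, train_fraction = 0.7,
                                 include_ablation = TRUE,
                                 progress = FALSE) {
  rows <- list()
  for (s in seeds) {
    ccfg <- drift_corpus_config(vocab_size = vocab_size,
                                n_docs_old = n_docs_old,
                                n_docs_new = n_docs_new,
                                drift_strength = delta,
                                seed = study_seed(s, 1))
    pairs <- generate_concept_pairs(ccfg, n_pairs)
    corpus <- generate_drift_corpus(ccfg, pairs)
    sp <- split_train_test(corpus, train_fraction, seed = study_seed(s, 2))
    train <- corpus[corpus$id %in% sp$train, ]
    test <- corpus[corpus$id %in% sp$test, ]
    tok <- whitespace_tokenizer(build_vocab(corpus$text))
    ecfg <- encoder_config(n_layers = layers, hidden_size = hidden,
                           n_heads = n_heads, ff_size = ff_size,
                           max_tokens = 32, seed = study_seed(s, 3))

    base <- train_mlm_baseline(train, ecfg, epochs = epochs, tokenizer = tok,
                               lr = lr, batch_size = batch_size,
                               seed = study_seed(s, 4))
    # the frozen anchor is a separate MLM-only run: anchoring the matched
    # encoder to the very baseline it is compared against would tether the
    # two models' similarity structures together
    anchor <- train_anchor(train, ecfg, epochs = epochs, tokenizer = tok,
                           lr = lr, batch_size = batch_size,
                           seed = study_seed(s, 9))
    tcfg <- tedi_train_config(lambda_adv = lambda_adv,
                              lambda_anchor = lambda_anchor,
                              epochs = epochs, lr_generator = lr,
                              lr_discriminator = lr_disc,
                              batch_size = batch_size,
                              seed = study_seed(s, 5))
    tedi_bundle <- train_tedi(train, anchor, tcfg)
    gen <- tedi_bundle$generator

    newtrain <- train[train$temporal_label == "NEW", ]
    ref <- train_mlm_baseline(newtrain, ecfg, epochs = epochs,
                              tokenizer = tok, lr = lr,
                              batch_size = batch_size,
                              seed = study_seed(s, 6))

    probe_base <- temporal_probe(base, corpus,
                                 split_seed = study_seed(s, 7))$accuracy
    probe_tedi <- temporal_probe(gen, corpus,
                                 split_seed = study_seed(s, 7))$accuracy
    mlm_base <- heldout_mlm_loss(base, test, seed = study_seed(s, 8))
    mlm_tedi <- heldout_mlm_loss(gen, test, seed = study_seed(s, 8))

    # mention contexts come from the full corpus: contexts are raw text,
    # and more mentions mean a less noisy similarity estimate
    rep_ref <- concept_similarity(ref, pairs, corpus = corpus,
                                  reference_tag = "new-period reference")
    corr_base <- future_relatedness_correlation(
      concept_similarity(base, pairs, corpus = corpus), rep_ref)
    corr_tedi <- future_relatedness_correlation(
      concept_similarity(gen, pairs, corpus = corpus), rep_ref)

    corr_noanchor <- NA_real_
    if (include_ablation) {
      tcfg0 <- tcfg
      tcfg0$lambda_anchor <- 0
      noanc <- train_tedi(train, anchor, tcfg0)$generator
      corr_noanchor <- future_relatedness_correlation(
        concept_similarity(noanc, pairs, corpus = corpus), rep_ref)
    }

    rows[[length(rows) + 1]] <- data.frame(
      seed = s,
      probe_baseline = probe_base, probe_tedi = probe_tedi,
      probe_drop = probe_base - probe_tedi,
      mlm_baseline = mlm_base, mlm_tedi = mlm_tedi,
      mlm_ratio = mlm_tedi / mlm_base,
      corr_baseline = corr_base, corr_tedi = corr_tedi,
      corr_noanchor = corr_noanchor)
    if (progress)
      message(sprintf(
        "seed %d: probe %.3f->%.3f  mlm ratio %.3f  corr %.3f/%.3f/%.3f",
        s, probe_base, probe_tedi, mlm_tedi / mlm_base,
        corr_base, corr_tedi, corr_noanchor))
  }
  do.call(rbind, rows)
}

#' Run the synthetic downstream prediction study
#'
#' Trains a small MLM encoder on a drifted corpus, builds a code vocabulary
#' from its tokens, generates patients with planted signal codes, fits an
#' oracle logistic model on code presence (the attainable-signal check),
#' trains the frozen-encoder LSTM classification head, and evaluates
#' held-out AUC overall and by group with bootstrap confidence intervals.
#'
#' @param seed Study seed.
#' @param n_patients Cohort size.
#' @param n_codes Code vocabulary size.
#' @param epochs_encoder,epochs_head Training epochs.
#' @param lr_head Head learning rate.
#' @param n_resamples Bootstrap resamples for the group report.
#' @param progress Print progress lines.
#' @return List with `oracle_auc`, `head_auc`, `report`
#'   (an `evaluation_report`), `checksum_unchanged`, and sizes.
#' @export
tedi_downstream_study <- function(seed = 1, n_patients = 2000, n_codes = 40,
                                  epochs_encoder = 3, epochs_head = 6,
                                  lr_head = 1e-3, n_resamples = 2000,
                                  progress = FALSE) {
  ccfg <- drift_corpus_config(vocab_size = 120, n_docs_old = 150,
                              n_docs_new = 150, drift_strength = 0.5,
                              seed = study_seed(seed, 11))
  corpus <- generate_drift_corpus(ccfg)
  tok <- whitespace_tokenizer(build_vocab(corpus$text))
  ecfg <- encoder_config(n_layers = 2, hidden_size = 64, n_heads = 2,
                         ff_size = 128, max_tokens = 32,
                         seed = study_seed(seed, 12))
  enc <- train_mlm_baseline(corpus, ecfg, epochs = epochs_encoder,
                            tokenizer = tok, lr = 1e-3,
                            seed = study_seed(seed, 13))
  if (progress) message("encoder ready")

  codes <- make_code_vocab(tok$vocab[-(1:4)], n_codes,
                           seed = study_seed(seed, 14))
  signal <- stats::setNames(c(2.5, 2, -2, 1.5, -1.5, 2, -2.5, 1), codes[1:8])
  pcfg <- synthetic_patient_config(
    n_patients = n_patients, female_fraction = 0.44, code_vocab = codes,
    outcome_kind = "BINARY", coefficient_map = signal,
    group_interaction = 0.5, intercept = -0.5,
    seed = study_seed(seed, 15))
  pts <- generate_patients(pcfg)

  idx <- local_seed(study_seed(seed, 16),
                    sample.int(n_patients, round(0.7 * n_patients)))
  tr <- pts[idx, ]
  te <- pts[-idx, ]

  # oracle: logistic regression on the one-hot code-presence matrix
  presence <- function(d) vapply(codes, function(cd)
    vapply(seq_len(nrow(d)), function(i)
      as.numeric(cd %in% c(d$prev_diagnoses[[i]], d$curr_diagnoses[[i]],
                           d$medications[[i]])), numeric(1)),
    numeric(nrow(d)))
  or_fit <- suppressWarnings(
    stats::glm.fit(cbind(1, presence(tr)), tr$outcome,
                   family = stats::binomial()))
  or_scores <- as.vector(cbind(1, presence(te)) %*% coef(or_fit))
  oracle_auc <- auc(te$outcome, or_scores)
  if (progress) message(sprintf("oracle AUC %.3f", oracle_auc))

  checksum_before <- enc_checksum(enc)
  hcfg <- head_config("classification", lstm_hidden = 64, mlp_hidden = 64,
                      epochs = epochs_head, lr = lr_head, batch_size = 32,
                      seed = study_seed(seed, 17))
  head_fit <- train_outcome_head(enc, tr, hcfg)
  report <- evaluate_by_group(head_fit, enc, te, n_resamples = n_resamples,
                              seed = study_seed(seed, 18))
  if (progress) message(sprintf("head AUC %.3f", report$overall$point))
  list(oracle_auc = oracle_auc,
       head_auc = report$overall$point,
       report = report,
       checksum_unchanged = identical(enc_checksum(enc), checksum_before),
       n_train = nrow(tr), n_test = nrow(te))
}
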