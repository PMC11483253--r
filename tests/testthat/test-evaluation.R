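test_that("held-out MLM loss is seed-deterministic and has its closed form", {
  corp <- small_corpus(6, 6, seed = 2, vocab_size = 8)
  # an encoder with a uniform prediction head scores exactly ln V
  enc <- fixed_head_encoder(rep(1 / 12, 12))
  expect_equal(heldout_mlm_loss(enc, corp, seed = 5), log(12))
  enc2 <- tiny_encoder(n_vocab = 8)
  expect_identical(heldout_mlm_loss(enc2, corp, seed = 5),
                   heldout_mlm_loss(enc2, corp, seed = 5))
  # different masking seeds give (generically) different losses
  expect_false(heldout_mlm_loss(enc2, corp, seed = 5) ==
                 heldout_mlm_loss(enc2, corp, seed = 6))
  expect_error(heldout_mlm_loss(enc2, corp[0, ], seed = 1), "empty")
})

test_that("MLM training beats random initialization on held-out loss", {
  full <- small_corpus(24, 24, seed = 3, vocab_size = 40)
  corp <- full[1:36, ]
  test_corp <- full[37:48, ]
  ecfg <- encoder_config(n_layers = 1, hidden_size = 8, n_heads = 2,
                         ff_size = 16, max_tokens = 16, seed = 6)
  tok <- whitespace_tokenizer(build_vocab(full$text))
  init <- encoder_init(ecfg, tok)
  trained <- train_mlm_baseline(corp, ecfg, epochs = 5, tokenizer = tok,
                                lr = 5e-3, batch_size = 8, seed = 2)
  expect_lt(heldout_mlm_loss(trained, test_corp, seed = 4),
            heldout_mlm_loss(init, test_corp, seed = 4))
})

test_that("the temporal probe collapses to the majority rate without signal", {
  # identical text everywhere -> identical embeddings -> majority prediction
  n_old <- 14; n_new <- 26
  corp <- tedi:::new_corpus(data.frame(
    id = sprintf("d%02d", 1:(n_old + n_new)),
    year = c(rep(2011, n_old), rep(2017, n_new)),
    text = "w001 w002 w003.", stringsAsFactors = FALSE))
  corp <- assign_temporal_labels(segment_sentences(corp))
  enc <- tiny_encoder(n_vocab = 8)
  pr <- temporal_probe(enc, corp, split_seed = 3, m = 4)
  test_ids <- setdiff(seq_len(40), tedi:::local_seed(3, sample.int(40, 28)))
  majority <- max(table(corp$temporal_label[test_ids])) / length(test_ids)
  expect_equal(pr$accuracy, majority)
  expect_equal(pr$n_train + pr$n_test, 40)
})

test_that("the probe needs two classes and two documents per class", {
  corp <- small_corpus(6, 6, seed = 2)
  single <- corp[corp$temporal_label == "OLD", ]
  enc <- tiny_encoder(n_vocab = 50)
  expect_error(temporal_probe(enc, single, 1), "both OLD and NEW")
})

test_that("label-shuffled probes hover at the majority rate", {
  corp <- small_corpus(40, 40, delta = 0.9, seed = 7, vocab_size = 60)
  enc <- tiny_encoder(n_vocab = 80, d = 8)
  enc$tokenizer <- whitespace_tokenizer(build_vocab(corp$text))
  enc <- encoder_init(enc$cfg, enc$tokenizer)
  shuffled <- corp
  shuffled$temporal_label <- withr::with_seed(5, sample(corp$temporal_label))
  accs <- vapply(1:3, function(s)
    temporal_probe(enc, shuffled, split_seed = s, m = 8)$accuracy, numeric(1))
  # expectation is the majority rate (0.5 here); allow Monte-Carlo spread
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("concept similarity is cosine on sentence embeddings", {
  enc <- tiny_encoder(n_vocab = 8, d = 8)
  pairs <- tibble::tibble(pair_id = c("p1", "p2"),
                          concept_a = c("w001", "w002 w003"),
                          concept_b = c("w001", "w004"))
  rep <- concept_similarity(enc, pairs)
  expect_equal(rep$similarities[1], 1)  # identical phrases
  # brute-force cosine oracle for the second pair
  va <- embed_sentence(enc, "w002 w003")
  vb <- embed_sentence(enc, "w004")
  num <- 0; na2 <- 0; nb2 <- 0
  for (k in seq_along(va)) {
    num <- num + va[k] * vb[k]; na2 <- na2 + va[k]^2; nb2 <- nb2 + vb[k]^2
  }
  expect_equal(rep$similarities[2], num / sqrt(na2 * nb2))
  expect_true(all(abs(rep$similarities) <= 1 + 1e-12))
})

test_that("rank correlation endpoints and a brute-force oracle agree", {
  mk <- function(s) structure(list(pair_ids = paste0("p", 1:5),
                                   similarities = s, reference_tag = ""),
                              class = "relatedness_report")
  s <- c(0.9, 0.1, 0.5, 0.3, 0.7)
  expect_equal(future_relatedness_correlation(mk(s), mk(s * 2 - 0.1)), 1)
  expect_equal(future_relatedness_correlation(mk(s), mk(-s)), -1)
  # brute-force Spearman: Pearson correlation of rank vectors
  t2 <- c(0.2, 0.8, 0.4, 0.9, 0.1)
  brute <- cor(rank(s), rank(t2))
  expect_equal(future_relatedness_correlation(mk(s), mk(t2)), brute)
  other <- mk(t2)
  other$pair_ids <- paste0("q", 1:5)
  expect_error(future_relatedness_correlation(mk(s), other), "different pairs")
  one <- structure(list(pair_ids = "p1", similarities = 0.5,
                        reference_tag = ""), class = "relatedness_report")
  expect_error(future_relatedness_correlation(one, one), ">= 2")
})

test_that("the default lambda grid has 43 points including (0.3, 0.3)", {
  g <- default_lambda_grid()
  expect_equal(nrow(g), 43)
  expect_true(any(abs(g$lambda_adv - 0.3) < 1e-9 &
                    abs(g$lambda_anchor - 0.3) < 1e-9))
  expect_true(all(g$lambda_adv + g$lambda_anchor < 1 + 1e-9))
})

test_that("grid search scores each point and breaks ties deterministically", {
  cfg <- drift_corpus_config(vocab_size = 60, n_docs_old = 10,
                             n_docs_new = 10, n_topics = 4, seed = 4)
  pairs <- generate_concept_pairs(cfg, 4)
  corp <- generate_drift_corpus(cfg, pairs)
  ecfg <- encoder_config(n_layers = 1, hidden_size = 8, n_heads = 2,
                         ff_size = 16, max_tokens = 16, seed = 2)
  anchor <- train_anchor(corp, ecfg, epochs = 1, lr = 1e-3, seed = 3)
  ref <- concept_similarity(anchor$encoder, pairs,
                            reference_tag = "reference")
  tmpl <- tedi_train_config(epochs = 1, lr_generator = 1e-3,
                            lr_discriminator = 1e-3, batch_size = 8, seed = 5)
  one <- data.frame(lambda_adv = 0.2, lambda_anchor = 0.1)
  gs <- lambda_grid_search(corp, anchor, one, pairs, ref, tmpl)
  expect_equal(nrow(gs$table), 1)
  expect_equal(gs$best$lambda_adv, 0.2)
  expect_error(lambda_grid_search(corp, anchor,
                                  data.frame(lambda_adv = 0.7,
                                             lambda_anchor = 0.5),
                                  pairs, ref, tmpl), "<= 1")
  expect_error(lambda_grid_search(corp, anchor, one[0, ], pairs, ref, tmpl),
               "empty")
})
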