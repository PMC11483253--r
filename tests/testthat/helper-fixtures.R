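# Shared fixtures: everything is generated in code at test time.

# A tiny word vocabulary and tokenizer shared across encoder tests.
tiny_vocab <- function(n = 8) sprintf("w%03d", seq_len(n))

tiny_tokenizer <- function(n = 8) whitespace_tokenizer(tiny_vocab(n))

tiny_encoder <- function(n_vocab = 8, d = 8, layers = 1, heads = 2,
                         ff = 16, maxlen = 12, seed = 3) {
  cfg <- encoder_config(n_layers = layers, hidden_size = d, n_heads = heads,
                        ff_size = ff, max_tokens = maxlen, seed = seed)
  encoder_init(cfg, tiny_tokenizer(n_vocab))
}

# Encoder whose MLM head produces a fixed output distribution: output
# weights are zeroed and the output bias set to log(probs), so every
# position predicts `probs` regardless of context.
fixed_head_encoder <- function(probs, ...) {
  enc <- tiny_encoder(n_vocab = length(probs) - 4, ...)
  V <- length(enc$tokenizer$vocab)
  d <- enc$cfg$hidden_size
  n <- length(enc$theta)
  enc$theta[(n - V * d - V + 1):n] <- 0          # out_W and out_b
  enc$theta[(n - V + 1):n] <- log(probs)          # out_b = log target dist
  enc
}

# A small labeled, segmented drift corpus.
small_corpus <- function(n_old = 30, n_new = 30, delta = 0.8, seed = 5,
                         vocab_size = 40, pairs = NULL) {
  cfg <- drift_corpus_config(vocab_size = vocab_size, n_docs_old = n_old,
                             n_docs_new = n_new, drift_strength = delta,
                             n_topics = 4, seed = seed)
  generate_drift_corpus(cfg, pairs)
}

# Document-level token-count matrix (bag of words) for oracle classifiers.
token_count_matrix <- function(corpus) {
  toks <- lapply(corpus$text,
                 function(t) strsplit(gsub("\\.", "", tolower(t)), "\\s+")[[1]])
  vocab <- sort(unique(unlist(toks)))
  X <- matrix(0, nrow(corpus), length(vocab), dimnames = list(NULL, vocab))
  for (i in seq_along(toks)) {
    tb <- table(toks[[i]])
    X[i, names(tb)] <- as.numeric(tb)
  }
  X
}

# Held-out accuracy of a ridge-logistic period classifier on token counts:
# the oracle for how separable a generated corpus is.
oracle_period_accuracy <- function(corpus, seed = 1) {
  X <- token_count_matrix(corpus)
  y <- factor(corpus$temporal_label)
  n <- nrow(X)
  idx <- withr::with_seed(seed, sample.int(n, round(0.7 * n)))
  fit <- glmnet::glmnet(X[idx, ], y[idx], family = "binomial", alpha = 0,
                        lambda = 0.01)
  mean(predict(fit, X[-idx, ], type = "class") == y[-idx])
}
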