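# Intrinsic evaluations: held-out MLM loss under a shared evaluation
# masking seed, the temporal probe (how much period information a linear
# classifier can still read off frozen embeddings), concept-pair cosine
# similarities, future semantic-relatedness rank correlation against a
# reference model, and the lambda grid search.

# n x (m*d) matrix of flattened abstract embeddings, one row per document.
abstract_matrix <- function(encoder, corpus, m) {
  d <- encoder$cfg$hidden_size
  ci <- cfg_ints(encoder$cfg, encoder$tokenizer)
  pool <- pooling_code(encoder$cfg)
  X <- matrix(0, nrow(corpus), m * d)
  sent_lists <- lapply(corpus$sentences, function(s) {
    stop_if(is.null(s), "corpus must be sentence-segmented first")
    tokenize_doc_sentences(encoder$tokenizer, head(s, m),
                           encoder$cfg$max_tokens)
  })
  ns <- vapply(sent_lists, length, 0L)
  flat <- lapply(unlist(sent_lists, recursive = FALSE),
                 function(x) as.integer(x - 1L))
  E <- cpp_pool_batch(encoder$theta, ci, flat, pool)
  pos <- cumsum(c(0, ns))
  for (i in seq_len(nrow(corpus))) {
    rows <- E[(pos[i] + 1):(pos[i] + ns[i]), , drop = FALSE]
    X[i, seq_len(ns[i] * d)] <- as.vector(t(rows))
  }
  X
}

#' Held-out masked-language-model loss
#'
#' Applies the MLM corruption with a fixed evaluation seed -- so every
#' model evaluated with the same seed sees identical corruptions -- and
#' returns the mean cross-entropy over masked positions.
#'
#' @param encoder A `tedi_encoder`.
#' @param corpus A segmented evaluation corpus (disjoint from training data;
#'   the caller's responsibility).
#' @param seed Evaluation masking seed.
#' @param mask_rate Masking rate.
#' @return Scalar loss.
#' @export
heldout_mlm_loss <- function(encoder, corpus, seed = 1234, mask_rate = 0.15) {
  stop_if(nrow(corpus) == 0, "empty evaluation set")
  batch <- local_seed(seed, {
    out <- list(); k <- 0
    for (i in seq_len(nrow(corpus))) {
      sents <- corpus$sentences[[i]]
      stop_if(is.null(sents), "corpus must be sentence-segmented first")
      for (ids in tokenize_doc_sentences(encoder$tokenizer, sents,
                                         encoder$cfg$max_tokens)) {
        k <- k + 1
        out[[k]] <- mask_tokens(ids, mask_rate, encoder$tokenizer)
      }
    }
    out
  })
  batch <- Filter(function(b) length(b$positions) > 0, batch)
  mlm_loss(encoder, batch)
}

#' Temporal probe: held-out period classification from frozen embeddings
#'
#' Freezes the encoder, computes flattened abstract embeddings of the
#' labeled documents, and trains a fresh linear classifier (logistic ridge)
#' on a seeded 70/30 split. The held-out accuracy measures how much period
#' information remains linearly recoverable: successful distribution
#' matching drives it toward the majority rate.
#'
#' @param encoder A `tedi_encoder`.
#' @param corpus Labeled, segmented corpus with at least 2 documents per
#'   class.
#' @param split_seed Seed of the 70/30 split.
#' @param m Abstract-embedding rows.
#' @param probe_lambda Ridge penalty of the probe.
#' @return A `probe_result` with `accuracy`, `n_train`, `n_test`, `seed`.
#' @export
temporal_probe <- function(encoder, corpus, split_seed = 1, m = 20,
                           probe_lambda = 1e-2) {
  lab <- corpus[corpus$temporal_label %in% c("OLD", "NEW"), , drop = FALSE]
  y <- lab$temporal_label
  stop_if(length(unique(y)) < 2, "probe needs both OLD and NEW documents")
  stop_if(min(table(y)) < 2, "probe needs >= 2 documents per class")
  X <- abstract_matrix(encoder, lab, m)
  n <- nrow(X)
  idx <- local_seed(split_seed, sample.int(n, round(0.7 * n)))
  Xtr <- X[idx, , drop = FALSE]
  if (all(Xtr == matrix(Xtr[1, ], nrow(Xtr), ncol(Xtr), byrow = TRUE))) {
    # identical embeddings carry no signal: the probe degenerates to the
    # majority-class predictor
    maj <- names(which.max(table(y[idx])))
    pred <- rep(maj, n - length(idx))
  } else {
    fit <- glmnet::glmnet(Xtr, factor(y[idx]), family = "binomial",
                          alpha = 0, lambda = probe_lambda,
                          standardize = TRUE)
    pred <- predict(fit, X[-idx, , drop = FALSE], type = "class")
  }
  structure(list(accuracy = mean(pred == y[-idx]),
                 n_train = length(idx), n_test = n - length(idx),
                 seed = as.integer(split_seed)),
            class = "probe_result")
}

#' Concept-pair similarities under an encoder
#'
#' Pair similarity is the cosine of the two concept vectors. With a corpus
#' supplied (the default mode when available), each concept vector is the
#' mean of the encoder's embeddings of every corpus sentence mentioning the
#' concept ("mention averaging"): contextual embeddings make co-occurring
#' concepts share contexts, so the similarity tracks distributional
#' relatedness far more reliably than embedding the bare concept phrase,
#' which at small scale reflects little beyond initialization. Without a
#' corpus, each concept is embedded as a standalone single-sentence input.
#' Pairs with a zero-norm vector (e.g. a concept never mentioned) are
#' dropped with a warning.
#'
#' @param encoder A `tedi_encoder`.
#' @param pairs Tibble with `pair_id`, `concept_a`, `concept_b`.
#' @param corpus Optional segmented corpus whose sentences supply concept
#'   mentions.
#' @param method `"auto"` (mention averaging when a corpus is given),
#'   `"mention_average"`, or `"standalone"`.
#' @param reference_tag Free-text tag recorded on the report.
#' @return A `relatedness_report` with `pair_ids` and `similarities`.
#' @export
concept_similarity <- function(encoder, pairs, corpus = NULL,
                               method = c("auto", "mention_average",
                                          "standalone"),
                               reference_tag = "") {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (is.null(corpus)) "standalone" else "mention_average"
  if (method == "mention_average") {
    stop_if(is.null(corpus), "mention averaging requires a corpus")
    sents <- unlist(corpus$sentences)
    concepts <- unique(c(pairs$concept_a, pairs$concept_b))
    hits <- lapply(concepts, function(cpt)
      which(grepl(paste0("\\b", cpt, "\\b"), sents)))
    used <- sort(unique(unlist(hits)))
    E <- if (length(used) > 0) embed_sentences(encoder, sents[used])
         else matrix(0, 0, encoder$cfg$hidden_size)
    row_of <- match(seq_along(sents), used)
    vecs <- t(vapply(hits, function(ix) {
      if (length(ix) == 0) return(numeric(encoder$cfg$hidden_size))
      colMeans(E[row_of[ix], , drop = FALSE])
    }, numeric(encoder$cfg$hidden_size)))
    rownames(vecs) <- concepts
    ea <- vecs[pairs$concept_a, , drop = FALSE]
    eb <- vecs[pairs$concept_b, , drop = FALSE]
  } else {
    ea <- embed_sentences(encoder, pairs$concept_a)
    eb <- embed_sentences(encoder, pairs$concept_b)
  }
  na <- sqrt(rowSums(ea^2)); nb <- sqrt(rowSums(eb^2))
  bad <- na == 0 | nb == 0
  if (any(bad)) warning("dropping ", sum(bad), " pair(s) with zero-norm vectors")
  sims <- rowSums(ea * eb) / (na * nb)
  structure(list(pair_ids = pairs$pair_id[!bad],
                 similarities = unname(sims[!bad]),
                 reference_tag = reference_tag),
            class = "relatedness_report")
}

#' Rank correlation between two similarity reports
#'
#' Spearman correlation (average ranks on ties) between a candidate
#' model's concept-pair similarities and those of a reference model --
#' typically one trained only on later-period text, so the correlation
#' measures how well the candidate anticipates future semantics.
#'
#' @param candidate,reference `relatedness_report`s over the same pairs.
#' @return Correlation in `[-1, 1]`.
#' @export
future_relatedness_correlation <- function(candidate, reference) {
  stop_if(!identical(candidate$pair_ids, reference$pair_ids),
          "reports cover different pairs")
  stop_if(length(candidate$pair_ids) < 2,
          "need >= 2 pairs for a rank correlation")
  cor(candidate$similarities, reference$similarities, method = "spearman")
}

#' Default lambda grid
#'
#' All `(lambda_adv, lambda_anchor)` combinations over `{0, 0.1, ..., 0.6}`
#' whose sum leaves the MLM term a strictly positive weight; 43 points,
#' including the default operating point (0.3, 0.3).
#'
#' @return Data frame with columns `lambda_adv`, `lambda_anchor`.
#' @export
default_lambda_grid <- function() {
  g <- expand.grid(lambda_adv = seq(0, 0.6, by = 0.1),
                   lambda_anchor = seq(0, 0.6, by = 0.1))
  g[round(g$lambda_adv + g$lambda_anchor, 9) < 1, , drop = FALSE]
}

#' Grid search over the loss weights
#'
#' Trains one distribution-matched encoder per grid point and scores each
#' by its future-relatedness rank correlation against the reference report;
#' ties break toward smaller `lambda_adv`, then smaller `lambda_anchor`.
#'
#' @param corpus Labeled, segmented training corpus.
#' @param anchor A `tedi_anchor`.
#' @param grid Data frame with `lambda_adv`, `lambda_anchor` columns.
#' @param pairs Concept pairs to score on.
#' @param reference A `relatedness_report` from the reference model.
#' @param cfg_template A [tedi_train_config()] supplying everything but the
#'   lambdas (reduced epochs are typical here).
#' @return List with `table` (grid plus `correlation`) and `best` (one row).
#' @export
lambda_grid_search <- function(corpus, anchor, grid, pairs, reference,
                               cfg_template = tedi_train_config()) {
  stop_if(nrow(grid) == 0, "empty grid")
  stop_if(any(grid$lambda_adv + grid$lambda_anchor > 1),
          "grid points must satisfy lambda_adv + lambda_anchor <= 1")
  corr <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- cfg_template
    cfg$lambda_adv <- grid$lambda_adv[i]
    cfg$lambda_anchor <- grid$lambda_anchor[i]
    bundle <- train_tedi(corpus, anchor, cfg)
    rep_i <- concept_similarity(bundle$generator, pairs)
    corr[i] <- future_relatedness_correlation(rep_i, reference)
  }
  tab <- cbind(grid, correlation = corr)
  ord <- order(-tab$correlation, tab$lambda_adv, tab$lambda_anchor)
  list(table = tab, best = tab[ord[1], , drop = FALSE])
}
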