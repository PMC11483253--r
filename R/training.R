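# Joint adversarial training: the encoder (generator) is trained on masked
# token prediction while a linear temporal discriminator tries to tell OLD
# from NEW documents from their abstract embeddings; the generator is
# simultaneously pushed to fool the discriminator and anchored to a frozen
# reference encoder by a Frobenius penalty. The MLM-only baseline trainer
# runs the identical loop with the adversary disabled, which is what makes
# the lambda = 0 degenerate-equivalence exact.

#' Training configuration for temporal distribution matching
#'
#' The composite generator objective is
#' `(1 - lambda_adv - lambda_anchor) * L_MLM + lambda_adv * L_adv' +
#'  lambda_anchor * L_A`, where `L_adv'` is the generator's adversarial
#' term (binary cross-entropy against flipped period labels by default).
#' The default operating point is `lambda_adv = lambda_anchor = 0.3`,
#' leaving the MLM term a weight of 0.4; both learning rates default to the
#' fine-tuning rate 2e-5 and training runs one batch at a time for 20
#' epochs.
#'
#' @param lambda_adv,lambda_anchor Loss weights in `[0, 1]` with
#'   `lambda_adv + lambda_anchor <= 1`.
#' @param epochs Training epochs.
#' @param lr_generator,lr_discriminator Adam learning rates.
#' @param batch_size Documents per batch.
#' @param seed Seed controlling shuffling and masking.
#' @param mlm_corpus_scope `"labeled_only"` (MLM term sees the OLD/NEW
#'   labeled subset) or `"all"` (unlabeled gap documents join the MLM term).
#' @param period_sample_weights Length-2 `(old, new)` weights applied to
#'   per-document adversarial loss contributions (ablation knob; 1:1
#'   default is a no-op).
#' @param mask_rate Masking rate for the MLM term.
#' @param m Abstract-embedding rows fed to the discriminator.
#' @param adv_mode `"label_flip"` (non-saturating, default) or `"negate"`
#'   (generator minimizes the negated discriminator loss).
#' @return A `tedi_train_config`.
#' @export
tedi_train_config <- function(lambda_adv = 0.3, lambda_anchor = 0.3,
                              epochs = 20,
                              lr_generator = 2e-5, lr_discriminator = 2e-5,
                              batch_size = 16, seed = 1,
                              mlm_corpus_scope = c("labeled_only", "all"),
                              period_sample_weights = c(old = 1, new = 1),
                              mask_rate = 0.15, m = 20,
                              adv_mode = c("label_flip", "negate")) {
  mlm_corpus_scope <- match.arg(mlm_corpus_scope)
  adv_mode <- match.arg(adv_mode)
  stop_if(lambda_adv < 0 || lambda_anchor < 0 ||
            lambda_adv + lambda_anchor > 1,
          "need lambda_adv, lambda_anchor >= 0 and lambda_adv + lambda_anchor <= 1")
  stop_if(length(period_sample_weights) != 2 || any(period_sample_weights <= 0),
          "period_sample_weights must be 2 positive numbers (old, new)")
  structure(list(lambda_adv = lambda_adv, lambda_anchor = lambda_anchor,
                 epochs = as.integer(epochs),
                 lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 mlm_corpus_scope = mlm_corpus_scope,
                 period_sample_weights = unname(period_sample_weights),
                 mask_rate = mask_rate, m = as.integer(m),
                 adv_mode = adv_mode),
            class = "tedi_train_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_update <- function(st, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(delta = lr * mhat / (sqrt(vhat) + eps), state = st)
}

# ---- internal training state ----------------------------------------------

tokenize_doc_sentences <- function(tokenizer, sentences, max_tokens) {
  lapply(sentences, function(s) {
    ids <- encode_sentence_ids(tokenizer, s)
    if (length(ids) > max_tokens) ids <- ids[seq_len(max_tokens)]
    ids
  })
}

label01 <- function(lab) c(OLD = 0, NEW = 1)[lab]

# One alternating step. `batch` is a list of entries:
#   list(sent_ids = list of [CLS]-prefixed 1-based id vectors,
#        label = 0/1/NA, anchor_emb = n_sent x d matrix or NULL)
# Consumes RNG for masking only. Returns updated state plus losses.
tedi_step_internal <- function(state, batch) {
  tc <- state$tcfg
  ci <- state$ci
  d <- ci[2]; m <- tc$m
  adversarial <- state$adversarial
  # -- masked-token corruption (the only RNG consumer) --
  corr <- list(); k <- 0
  for (e in batch) {
    for (ids in e$sent_ids) {
      k <- k + 1
      corr[[k]] <- mask_tokens(ids, tc$mask_rate, state$tok)
    }
  }
  corr <- Filter(function(b) length(b$positions) > 0, corr)
  stop_if(length(corr) == 0, "batch produced no masked positions")
  a <- mlm_batch_args(corr)
  mlm <- cpp_mlm_batch(state$theta, ci, a$sents, a$tpos, a$tids, TRUE)
  l_mlm <- mlm$loss
  w_mlm <- 1 - tc$lambda_adv - tc$lambda_anchor
  l_adv <- NA_real_; l_adv_gen <- NA_real_; l_anc <- NA_real_
  grad <- NULL

  if (adversarial) {
    lab_idx <- which(!is.na(vapply(batch, `[[`, 0, "label")))
    if (length(lab_idx) > 0) {
      ents <- batch[lab_idx]
      y <- vapply(ents, `[[`, 0, "label")
      nb <- length(ents)
      wts <- ifelse(y == 0, tc$period_sample_weights[1],
                    tc$period_sample_weights[2])
      wn <- wts / mean(wts)
      # generator abstract embeddings (first m sentences per doc)
      sent_lists <- lapply(ents, function(e) head(e$sent_ids, m))
      ns <- vapply(sent_lists, length, 0L)
      flat_sents <- lapply(unlist(sent_lists, recursive = FALSE),
                           function(x) as.integer(x - 1L))
      E <- cpp_pool_batch(state$theta, ci, flat_sents, state$pool)
      X <- matrix(0, nb, m * d)
      pos <- cumsum(c(0, ns))
      for (i in seq_len(nb)) {
        rows <- E[(pos[i] + 1):(pos[i] + ns[i]), , drop = FALSE]
        X[i, seq_len(ns[i] * d)] <- as.vector(t(rows))
      }
      # (1) discriminator update on the current generator's embeddings
      z <- as.vector(X %*% state$disc_w) + state$disc_b
      p <- sigmoid(z)
      l_adv <- adversarial_loss(p, y, wn)
      dz <- (p - y) * wn / nb
      up_d <- adam_update(state$adam_d,
                          c(as.vector(crossprod(X, dz)), sum(dz)),
                          tc$lr_discriminator)
      state$adam_d <- up_d$state
      nw <- length(state$disc_w)
      state$disc_w <- state$disc_w - up_d$delta[seq_len(nw)]
      state$disc_b <- state$disc_b - up_d$delta[nw + 1]
      # (2) generator update against the (frozen) updated discriminator
      upstream <- matrix(0, nrow(E), d)
      if (tc$lambda_adv > 0 || tc$lambda_anchor > 0) {
        if (tc$lambda_adv > 0) {
          z2 <- as.vector(X %*% state$disc_w) + state$disc_b
          p2 <- sigmoid(z2)
          if (tc$adv_mode == "label_flip") {
            l_adv_gen <- adversarial_loss(p2, 1 - y, wn)
            dz2 <- (p2 - (1 - y)) * wn / nb
          } else {
            l_adv_gen <- -adversarial_loss(p2, y, wn)
            dz2 <- -(p2 - y) * wn / nb
          }
          for (i in seq_len(nb)) {
            gX <- matrix(state$disc_w[seq_len(ns[i] * d)] * dz2[i],
                         nrow = ns[i], ncol = d, byrow = TRUE)
            upstream[(pos[i] + 1):(pos[i] + ns[i]), ] <-
              upstream[(pos[i] + 1):(pos[i] + ns[i]), ] + tc$lambda_adv * gX
          }
        }
        if (tc$lambda_anchor > 0) {
          norms <- numeric(nb)
          for (i in seq_len(nb)) {
            A <- ents[[i]]$anchor_emb
            G <- E[(pos[i] + 1):(pos[i] + ns[i]), , drop = FALSE]
            Dm <- G - A[seq_len(ns[i]), , drop = FALSE]
            norms[i] <- sqrt(sum(Dm^2))
            if (norms[i] > 0) {
              upstream[(pos[i] + 1):(pos[i] + ns[i]), ] <-
                upstream[(pos[i] + 1):(pos[i] + ns[i]), ] +
                tc$lambda_anchor * Dm / (norms[i] * nb)
            }
          }
          l_anc <- mean(norms)
        }
        g_emb <- cpp_pool_backward(state$theta, ci, flat_sents, upstream,
                                   state$pool)
        grad <- w_mlm * mlm$grad + g_emb
      }
    }
  }
  if (is.null(grad)) grad <- if (w_mlm == 1) mlm$grad else w_mlm * mlm$grad
  up_g <- adam_update(state$adam_g, grad, tc$lr_generator)
  state$adam_g <- up_g$state
  state$theta <- state$theta - up_g$delta
  composite <- w_mlm * l_mlm +
    (if (!is.na(l_adv_gen)) tc$lambda_adv * l_adv_gen else 0) +
    (if (!is.na(l_anc)) tc$lambda_anchor * l_anc else 0)
  list(state = state,
       losses = c(mlm = l_mlm, adv = l_adv, adv_gen = l_adv_gen,
                  anchor = l_anc, composite = composite))
}

make_train_state <- function(encoder, tcfg, adversarial, disc = NULL) {
  ci <- cfg_ints(encoder$cfg, encoder$tokenizer)
  lay_total <- length(encoder$theta)
  d <- encoder$cfg$hidden_size
  disc <- disc %||% temporal_discriminator(tcfg$m, d)
  list(theta = encoder$theta, tok = encoder$tokenizer,
       enc_cfg = encoder$cfg, tcfg = tcfg, ci = ci,
       pool = pooling_code(encoder$cfg),
       disc_w = disc$weights, disc_b = disc$bias,
       adam_g = adam_init(lay_total),
       adam_d = adam_init(tcfg$m * d + 1),
       adversarial = adversarial)
}

prepare_doc_entries <- function(corpus, tokenizer, max_tokens, labels = TRUE) {
  lapply(seq_len(nrow(corpus)), function(i) {
    sents <- corpus$sentences[[i]]
    stop_if(is.null(sents), "corpus must be sentence-segmented first")
    list(sent_ids = tokenize_doc_sentences(tokenizer, sents, max_tokens),
         label = if (labels) unname(label01(corpus$temporal_label[i]))
                 else NA_real_,
         anchor_emb = NULL)
  })
}

attach_anchor_embeddings <- function(entries, anchor, ci, pool, m) {
  theta_a <- anchor_encoder(anchor)$theta
  for (i in seq_along(entries)) {
    if (is.na(entries[[i]]$label)) next
    sl <- head(entries[[i]]$sent_ids, m)
    A <- cpp_pool_batch(theta_a, ci,
                        lapply(sl, function(x) as.integer(x - 1L)), pool)
    entries[[i]]$anchor_emb <- A
  }
  entries
}

run_train_loop <- function(corpus, encoder, tcfg, anchor = NULL,
                           adversarial = TRUE) {
  labeled <- corpus$temporal_label %in% c("OLD", "NEW")
  if (adversarial) {
    stop_if(sum(corpus$temporal_label == "OLD") == 0 ||
              sum(corpus$temporal_label == "NEW") == 0,
            "adversarial training needs both OLD and NEW documents")
    use <- if (tcfg$mlm_corpus_scope == "all") rep(TRUE, nrow(corpus)) else labeled
  } else {
    use <- rep(TRUE, nrow(corpus))
  }
  sub <- corpus[use, , drop = FALSE]
  entries <- prepare_doc_entries(sub, encoder$tokenizer,
                                 encoder$cfg$max_tokens,
                                 labels = adversarial)
  if (adversarial && !is.null(anchor) && tcfg$lambda_anchor > 0) {
    entries <- attach_anchor_embeddings(
      entries, anchor, cfg_ints(encoder$cfg, encoder$tokenizer),
      pooling_code(encoder$cfg), tcfg$m)
  }
  state <- make_train_state(encoder, tcfg, adversarial)
  n <- length(entries)
  hist <- vector("list", tcfg$epochs)
  local_seed(tcfg$seed, {
    for (ep in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
      acc <- NULL
      for (b in batches) {
        res <- tedi_step_internal(state, entries[b])
        state <- res$state
        acc <- rbind(acc, res$losses)
      }
      hist[[ep]] <- colMeans(acc, na.rm = TRUE)
    }
  })
  history <- as.data.frame(do.call(rbind, hist))
  if (tcfg$epochs > 0) history$epoch <- seq_len(tcfg$epochs)
  list(state = state, history = history)
}

#' Train an encoder with temporal distribution matching
#'
#' Runs the alternating per-batch updates of [tedi_step()] over shuffled
#' documents for `cfg$epochs` epochs: first the discriminator takes a
#' gradient step on the adversarial loss, then the generator takes a step
#' on the composite objective with the discriminator frozen. Deterministic
#' given the seeds in `enc_cfg` and `cfg`.
#'
#' @param corpus A labeled, segmented `tedi_corpus` with at least one OLD
#'   and one NEW document.
#' @param anchor A `tedi_anchor` (frozen, same architecture); may be `NULL`
#'   only when `cfg$lambda_anchor == 0`.
#' @param cfg A [tedi_train_config()].
#' @param enc_cfg An [encoder_config()]; defaults to the anchor's config.
#' @param tokenizer Tokenizer; defaults to the anchor's.
#' @return A `tedi_bundle` with `generator`, `discriminator`, `anchor`,
#'   `config` and per-epoch `history` of `(mlm, adv, adv_gen, anchor,
#'   composite)` losses.
#' @export
train_tedi <- function(corpus, anchor, cfg = tedi_train_config(),
                       enc_cfg = NULL, tokenizer = NULL) {
  stopifnot(inherits(cfg, "tedi_train_config"))
  stop_if(is.null(anchor) && cfg$lambda_anchor > 0,
          "an anchor model is required when lambda_anchor > 0")
  if (!is.null(anchor)) {
    enc_cfg <- enc_cfg %||% anchor_encoder(anchor)$cfg
    tokenizer <- tokenizer %||% anchor_encoder(anchor)$tokenizer
  }
  stop_if(is.null(enc_cfg) || is.null(tokenizer),
          "enc_cfg and tokenizer are required when no anchor is given")
  encoder <- encoder_init(enc_cfg, tokenizer)
  res <- run_train_loop(corpus, encoder, cfg, anchor, adversarial = TRUE)
  encoder$theta <- res$state$theta
  encoder$history <- res$history
  disc <- temporal_discriminator(cfg$m, enc_cfg$hidden_size)
  disc$weights <- res$state$disc_w
  disc$bias <- res$state$disc_b
  structure(list(generator = encoder, discriminator = disc, anchor = anchor,
                 config = cfg, history = res$history),
            class = "tedi_bundle")
}

#' One alternating training step on a labeled batch
#'
#' Exposed for inspection and testing: performs the discriminator
#' sub-update followed by the generator sub-update on one batch of labeled,
#' segmented documents, and returns the updated bundle with the per-batch
#' losses.
#'
#' @param bundle A `tedi_bundle` (from [train_tedi()], possibly with 0
#'   epochs).
#' @param batch A `tedi_corpus` subset whose documents all carry OLD/NEW
#'   labels.
#' @return List with `bundle` and `losses` (`mlm`, `adv`, `adv_gen`,
#'   `anchor`, `composite`).
#' @export
tedi_step <- function(bundle, batch) {
  stopifnot(inherits(bundle, "tedi_bundle"))
  stop_if(any(!batch$temporal_label %in% c("OLD", "NEW")),
          "all batch documents must carry OLD/NEW labels")
  gen <- bundle$generator
  entries <- prepare_doc_entries(batch, gen$tokenizer, gen$cfg$max_tokens)
  if (!is.null(bundle$anchor) && bundle$config$lambda_anchor > 0) {
    entries <- attach_anchor_embeddings(
      entries, bundle$anchor, cfg_ints(gen$cfg, gen$tokenizer),
      pooling_code(gen$cfg), bundle$config$m)
  }
  state <- make_train_state(gen, bundle$config, TRUE, bundle$discriminator)
  state$adam_g <- bundle$opt_g %||% state$adam_g
  state$adam_d <- bundle$opt_d %||% state$adam_d
  res <- tedi_step_internal(state, entries)
  bundle$generator$theta <- res$state$theta
  bundle$discriminator$weights <- res$state$disc_w
  bundle$discriminator$bias <- res$state$disc_b
  bundle$opt_g <- res$state$adam_g
  bundle$opt_d <- res$state$adam_d
  list(bundle = bundle, losses = res$losses)
}

#' Train an MLM-only baseline encoder
#'
#' Masked-language-model training over all documents, temporal labels
#' ignored; the same loop as [train_tedi()] with the adversary disabled, so
#' a TeDi run with `lambda_adv = lambda_anchor = 0` and matched seeds
#' reproduces this trainer's weights exactly.
#'
#' @param corpus A segmented `tedi_corpus`.
#' @param cfg An [encoder_config()].
#' @param epochs Training epochs.
#' @param tokenizer Tokenizer (built from the corpus if omitted).
#' @param lr,batch_size,mask_rate Optimization settings.
#' @param seed Shuffle/masking seed.
#' @return A `tedi_encoder` with per-epoch MLM loss history.
#' @export
train_mlm_baseline <- function(corpus, cfg, epochs, tokenizer = NULL,
                               lr = 2e-5, batch_size = 16,
                               mask_rate = 0.15, seed = 1) {
  stop_if(nrow(corpus) == 0, "empty corpus")
  if (is.null(tokenizer)) tokenizer <- whitespace_tokenizer(build_vocab(corpus$text))
  tcfg <- tedi_train_config(lambda_adv = 0, lambda_anchor = 0,
                            epochs = epochs, lr_generator = lr,
                            lr_discriminator = lr, batch_size = batch_size,
                            seed = seed, mask_rate = mask_rate)
  encoder <- encoder_init(cfg, tokenizer)
  res <- run_train_loop(corpus, encoder, tcfg, anchor = NULL,
                        adversarial = FALSE)
  encoder$theta <- res$state$theta
  encoder$history <- res$history
  encoder
}
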