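# Downstream task heads over a frozen embedder: a regression head
# (continuous outcome, e.g. length of stay) and a classification head
# (binary outcome, e.g. unplanned readmission). Code-description sequences
# are embedded by the frozen encoder, aggregated by an LSTM whose weights
# are shared across all sequences of a task, concatenated with static
# features (and, for regression, the current primary-diagnosis embedding),
# and fed to a 2-layer feed-forward model. Only the head trains; the
# encoder's parameter checksum is asserted unchanged.

#' Configuration of a downstream task head
#'
#' Per-task defaults mirror the standard settings for these two tasks:
#' regression trains for 10 epochs at learning rate 1e-3 with mean squared
#' error; classification for 4 epochs at 1e-5 with binary cross-entropy.
#'
#' @param task `"regression"` or `"classification"`.
#' @param lstm_hidden LSTM hidden size.
#' @param mlp_hidden Width of the feed-forward hidden layer.
#' @param epochs,lr Training epochs and Adam learning rate (per-task
#'   defaults when `NULL`).
#' @param batch_size Patients per batch.
#' @param include_group Include the group indicator among the static
#'   features (default TRUE; the group is predictive and removing it is a
#'   deliberate choice).
#' @param seed Seed for head initialization and shuffling.
#' @return A `head_config`.
#' @export
head_config <- function(task = c("regression", "classification"),
                        lstm_hidden = 64, mlp_hidden = 64,
                        epochs = NULL, lr = NULL, batch_size = 32,
                        include_group = TRUE, seed = 1) {
  task <- match.arg(task)
  epochs <- epochs %||% if (task == "regression") 10L else 4L
  lr <- lr %||% if (task == "regression") 1e-3 else 1e-5
  stop_if(lstm_hidden <= 0 || mlp_hidden <= 0, "sizes must be positive")
  structure(list(task = task, lstm_hidden = as.integer(lstm_hidden),
                 mlp_hidden = as.integer(mlp_hidden),
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 include_group = include_group, seed = as.integer(seed)),
            class = "head_config")
}

# ---- LSTM (batched, shared weights across sequence slots) -----------------

lstm_params <- function(d_in, h) {
  k <- 1 / sqrt(h)
  p <- list(Wx = matrix(runif(d_in * 4 * h, -k, k), d_in, 4 * h),
            Wh = matrix(runif(h * 4 * h, -k, k), h, 4 * h),
            b = numeric(4 * h))
  p$b[(h + 1):(2 * h)] <- 1  # forget-gate bias
  p
}

# seqs: list of (len x d_in) matrices (len may be 0 -> zero output).
lstm_forward <- function(par, seqs, h) {
  B <- length(seqs)
  lens <- vapply(seqs, nrow, 0L)
  Tmax <- max(lens, 0L)
  d_in <- nrow(par$Wx)
  H <- matrix(0, B, h); C <- matrix(0, B, h)
  cache <- vector("list", Tmax)
  for (t in seq_len(Tmax)) {
    Xt <- matrix(0, B, d_in)
    act <- lens >= t
    for (i in which(act)) Xt[i, ] <- seqs[[i]][t, ]
    pre <- Xt %*% par$Wx + H %*% par$Wh
    pre <- sweep(pre, 2, par$b, "+")
    ig <- sigmoid(pre[, 1:h, drop = FALSE])
    fg <- sigmoid(pre[, (h + 1):(2 * h), drop = FALSE])
    gg <- tanh(pre[, (2 * h + 1):(3 * h), drop = FALSE])
    og <- sigmoid(pre[, (3 * h + 1):(4 * h), drop = FALSE])
    Cn <- fg * C + ig * gg
    tc <- tanh(Cn)
    Hn <- og * tc
    m <- as.numeric(act)
    cache[[t]] <- list(Xt = Xt, Hp = H, Cp = C, ig = ig, fg = fg, gg = gg,
                       og = og, tc = tc, m = m)
    H <- m * Hn + (1 - m) * H
    C <- m * Cn + (1 - m) * C
  }
  list(out = H, cache = cache, lens = lens)
}

# Backprop dOut (B x h) through the cached forward; returns parameter grads.
lstm_backward <- function(par, fwd, dOut, h) {
  B <- nrow(dOut)
  d_in <- nrow(par$Wx)
  dWx <- matrix(0, d_in, 4 * h); dWh <- matrix(0, h, 4 * h); db <- numeric(4 * h)
  dH <- dOut; dC <- matrix(0, B, h)
  for (t in rev(seq_along(fwd$cache))) {
    cc <- fwd$cache[[t]]
    m <- cc$m
    dHn <- m * dH; dHp_pass <- (1 - m) * dH
    dCn <- m * dC; dCp_pass <- (1 - m) * dC
    dog <- dHn * cc$tc
    dCn <- dCn + dHn * cc$og * (1 - cc$tc^2)
    dfg <- dCn * cc$Cp
    dig <- dCn * cc$gg
    dgg <- dCn * cc$ig
    dCp <- dCn * cc$fg + dCp_pass
    dpre <- cbind(dig * cc$ig * (1 - cc$ig),
                  dfg * cc$fg * (1 - cc$fg),
                  dgg * (1 - cc$gg^2),
                  dog * cc$og * (1 - cc$og))
    dWx <- dWx + crossprod(cc$Xt, dpre)
    dWh <- dWh + crossprod(cc$Hp, dpre)
    db <- db + colSums(dpre)
    dH <- dpre %*% t(par$Wh) + dHp_pass
    dC <- dCp
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# ---- embedding cache -------------------------------------------------------

# Embed every unique code description once with the frozen encoder.
code_embedding_cache <- function(encoder, records) {
  codes <- unique(c(unlist(records$prev_diagnoses),
                    unlist(records$curr_diagnoses),
                    unlist(records$medications),
                    records$primary_diagnosis))
  codes <- codes[!is.na(codes) & nzchar(codes)]
  E <- embed_sentences(encoder, codes)
  rownames(E) <- codes
  E
}

seq_to_matrix <- function(cache, codes, d) {
  if (length(codes) == 0) return(matrix(0, 0, d))
  cache[codes, , drop = FALSE]
}

head_sequence_slots <- function(task) {
  if (task == "classification") c("prev_diagnoses", "curr_diagnoses", "medications")
  else "prev_diagnoses"
}

static_features <- function(records, include_group) {
  X <- cbind(age = (records$age - 60) / 15)
  if (include_group) X <- cbind(X, group = as.numeric(records$group == "F"))
  X
}

# ---- head training ---------------------------------------------------------

head_forward <- function(head, cache, records, want_cache = FALSE) {
  h <- head$cfg$lstm_hidden
  d <- head$d
  slots <- head_sequence_slots(head$cfg$task)
  B <- nrow(records)
  outs <- list(); fwds <- list()
  for (s in slots) {
    seqs <- lapply(records[[s]], function(cs) {
      if (length(cs) == 0) warning("empty sequence aggregated as zero vector")
      seq_to_matrix(cache, cs, d)
    })
    fw <- lstm_forward(head$lstm, seqs, h)
    outs[[s]] <- fw$out
    fwds[[s]] <- fw
  }
  R <- do.call(cbind, outs)
  if (head$cfg$task == "regression")
    R <- cbind(R, seq_to_matrix(cache, records$primary_diagnosis, d))
  R <- cbind(R, static_features(records, head$cfg$include_group))
  H1 <- pmax(R %*% head$mlp$W1 + matrix(head$mlp$b1, B, length(head$mlp$b1),
                                        byrow = TRUE), 0)
  z <- as.vector(H1 %*% head$mlp$W2 + head$mlp$b2)
  if (want_cache) list(z = z, R = R, H1 = H1, fwds = fwds) else z
}

head_param_vec <- function(head) {
  c(as.vector(head$lstm$Wx), as.vector(head$lstm$Wh), head$lstm$b,
    as.vector(head$mlp$W1), head$mlp$b1, as.vector(head$mlp$W2), head$mlp$b2)
}

head_set_params <- function(head, v) {
  sz <- function(x) length(x)
  k <- 0
  take <- function(obj) {
    n <- length(obj)
    out <- v[(k + 1):(k + n)]
    k <<- k + n
    if (is.matrix(obj)) matrix(out, nrow(obj), ncol(obj)) else out
  }
  head$lstm$Wx <- take(head$lstm$Wx)
  head$lstm$Wh <- take(head$lstm$Wh)
  head$lstm$b <- take(head$lstm$b)
  head$mlp$W1 <- take(head$mlp$W1)
  head$mlp$b1 <- take(head$mlp$b1)
  head$mlp$W2 <- take(head$mlp$W2)
  head$mlp$b2 <- take(head$mlp$b2)
  head
}

head_grad_vec <- function(head, cache, records, y) {
  fc <- head_forward(head, cache, records, want_cache = TRUE)
  B <- nrow(records)
  if (head$cfg$task == "regression") {
    loss <- mean((fc$z - y)^2)
    dz <- 2 * (fc$z - y) / B
  } else {
    p <- sigmoid(fc$z)
    loss <- mean(-(y * log(clip01(p)) + (1 - y) * log(clip01(1 - p))))
    dz <- (p - y) / B
  }
  dW2 <- crossprod(fc$H1, dz)
  db2 <- sum(dz)
  dH1 <- (cbind(dz) %*% t(head$mlp$W2)) * (fc$H1 > 0)
  dW1 <- crossprod(fc$R, dH1)
  db1 <- colSums(dH1)
  dR <- dH1 %*% t(head$mlp$W1)
  h <- head$cfg$lstm_hidden
  slots <- head_sequence_slots(head$cfg$task)
  dWx <- matrix(0, nrow(head$lstm$Wx), ncol(head$lstm$Wx))
  dWh <- matrix(0, h, 4 * h); db <- numeric(4 * h)
  for (si in seq_along(slots)) {
    dOut <- dR[, ((si - 1) * h + 1):(si * h), drop = FALSE]
    g <- lstm_backward(head$lstm, fc$fwds[[slots[si]]], dOut, h)
    dWx <- dWx + g$Wx; dWh <- dWh + g$Wh; db <- db + g$b
  }
  list(loss = loss,
       grad = c(as.vector(dWx), as.vector(dWh), db,
                as.vector(dW1), db1, as.vector(dW2), db2))
}

#' Train a downstream outcome head over a frozen encoder
#'
#' Embeds each code description with the frozen encoder, aggregates each
#' sequence with a shared-weight LSTM, concatenates static features (and
#' the current primary-diagnosis embedding for regression), and trains the
#' 2-layer feed-forward output model with Adam. Regression minimizes mean
#' squared error; classification minimizes binary cross-entropy. The
#' encoder's checksum is verified unchanged after training.
#'
#' @param encoder A frozen `tedi_encoder`.
#' @param records A `tedi_patients` training set.
#' @param cfg A [head_config()].
#' @return A `tedi_head` containing the trained LSTM/MLP weights, the code
#'   embedding cache, per-epoch loss history and the encoder checksum.
#' @export
train_outcome_head <- function(encoder, records, cfg) {
  stopifnot(inherits(cfg, "head_config"))
  y <- records$outcome
  if (cfg$task == "classification")
    stop_if(!all(y %in% c(0, 1)), "classification requires 0/1 outcomes")
  else stop_if(!is.numeric(y), "regression requires a numeric outcome")
  checksum_before <- enc_checksum(encoder)
  cache <- code_embedding_cache(encoder, records)
  d <- encoder$cfg$hidden_size
  n_static <- ncol(static_features(records[1, , drop = FALSE], cfg$include_group))
  n_slots <- length(head_sequence_slots(cfg$task))
  p_in <- n_slots * cfg$lstm_hidden + n_static +
    if (cfg$task == "regression") d else 0
  head <- local_seed(cfg$seed, {
    k <- 1 / sqrt(p_in)
    list(cfg = cfg, d = d,
         lstm = lstm_params(d, cfg$lstm_hidden),
         mlp = list(W1 = matrix(runif(p_in * cfg$mlp_hidden, -k, k),
                                p_in, cfg$mlp_hidden),
                    b1 = numeric(cfg$mlp_hidden),
                    W2 = matrix(runif(cfg$mlp_hidden, -0.1, 0.1),
                                cfg$mlp_hidden, 1),
                    b2 = 0))
  })
  class(head) <- "tedi_head"
  theta <- head_param_vec(head)
  ad <- adam_init(length(theta))
  n <- nrow(records)
  hist <- numeric(cfg$epochs)
  local_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        b <- batches[[bi]]
        g <- head_grad_vec(head, cache, records[b, , drop = FALSE], y[b])
        up <- adam_update(ad, g$grad, cfg$lr)
        ad <- up$state
        theta <- theta - up$delta
        head <- head_set_params(head, theta)
        losses[bi] <- g$loss
      }
      hist[ep] <- mean(losses)
    }
  })
  head$history <- hist
  head$code_cache <- cache
  head$encoder_checksum <- checksum_before
  stop_if(!identical(enc_checksum(encoder), checksum_before),
          "encoder parameters changed during head training")
  head
}

#' Patient representation under a trained head
#'
#' The concatenation fed to the head's feed-forward model: one shared-LSTM
#' aggregate per sequence slot, the current primary-diagnosis embedding
#' (regression only), then static features.
#'
#' @param encoder The frozen `tedi_encoder`.
#' @param record A single-row `tedi_patients` subset.
#' @param head A trained `tedi_head`.
#' @return Numeric representation vector.
#' @export
build_patient_representation <- function(encoder, record, head) {
  stop_if(nrow(record) != 1, "expected exactly one patient record")
  cache <- code_cache_for(head, encoder, record)
  fc <- head_forward(head, cache, record, want_cache = TRUE)
  as.numeric(fc$R[1, ])
}

# Extend the head's training-time cache with any unseen codes.
code_cache_for <- function(head, encoder, records) {
  cache <- head$code_cache
  codes <- unique(c(unlist(records$prev_diagnoses),
                    unlist(records$curr_diagnoses),
                    unlist(records$medications),
                    records$primary_diagnosis))
  new <- setdiff(codes, rownames(cache))
  if (length(new) > 0) {
    E <- embed_sentences(encoder, new)
    rownames(E) <- new
    cache <- rbind(cache, E)
  }
  cache
}

#' Predict outcomes with a trained head
#'
#' @param head A `tedi_head`.
#' @param encoder The frozen encoder used at training time.
#' @param records A `tedi_patients` set.
#' @return Numeric scores: predicted outcome (regression) or predicted
#'   probability (classification).
#' @export
predict_head <- function(head, encoder, records) {
  cache <- code_cache_for(head, encoder, records)
  z <- head_forward(head, cache, records)
  if (head$cfg$task == "classification") sigmoid(z) else z
}

#' Group-wise evaluation of a downstream head
#'
#' Per-group and overall metric -- AUC for classification, mean absolute
#' error for regression -- with seeded percentile bootstrap confidence
#' intervals, plus pairwise metric gaps between groups. Groups with fewer
#' than 2 records are reported as insufficient.
#'
#' @param head A trained `tedi_head`.
#' @param encoder The frozen encoder.
#' @param records Test-set `tedi_patients`.
#' @param group_field Column holding the group label.
#' @param n_resamples Bootstrap resamples (default 2000).
#' @param seed Bootstrap seed.
#' @return An `evaluation_report`: `metric_name`, `overall`, `groups`
#'   (each with `point`, `lo`, `hi`, `n`), and `gaps`.
#' @export
evaluate_by_group <- function(head, encoder, records, group_field = "group",
                              n_resamples = 2000, seed = 1) {
  stop_if(!group_field %in% names(records),
          "unknown group field: ", group_field)
  scores <- predict_head(head, encoder, records)
  y <- records$outcome
  metric_name <- if (head$cfg$task == "classification") "auc" else "mae"
  mfun <- if (metric_name == "auc") {
    function(df) auc(df$y, df$s)
  } else {
    function(df) mean(abs(df$s - df$y))
  }
  df <- data.frame(y = y, s = scores, g = records[[group_field]])
  eval_on <- function(sub, seed_k) {
    ci <- bootstrap_ci(mfun, sub[, c("y", "s")], n_resamples = n_resamples,
                       seed = seed_k)
    list(point = ci$point, lo = ci$lo, hi = ci$hi, n = nrow(sub))
  }
  overall <- eval_on(df, seed)
  groups <- list()
  for (g in sort(unique(df$g))) {
    sub <- df[df$g == g, , drop = FALSE]
    groups[[g]] <- if (nrow(sub) < 2 ||
                       (metric_name == "auc" && length(unique(sub$y)) < 2)) {
      list(point = NA_real_, lo = NA_real_, hi = NA_real_, n = nrow(sub),
           insufficient = TRUE)
    } else {
      eval_on(sub, seed + match(g, sort(unique(df$g))))
    }
  }
  gaps <- list()
  gn <- names(groups)
  if (length(gn) >= 2) {
    for (i in seq_along(gn)) for (j in seq_along(gn)) {
      if (i < j) {
        gaps[[paste0(gn[i], "-", gn[j])]] <-
          groups[[gn[i]]]$point - groups[[gn[j]]]$point
      }
    }
  }
  structure(list(metric_name = metric_name, overall = overall,
                 groups = groups, gaps = gaps,
                 n_resamples = n_resamples, seed = seed),
            class = "evaluation_report")
}
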