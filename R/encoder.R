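# The generator: a small transformer encoder with a masked-token prediction
# head. Parameters live in one flat numeric vector whose layout is defined
# by the compiled core; this file provides configuration, initialization,
# masking, loss evaluation and sentence/abstract embedding.

#' Encoder configuration
#'
#' Defaults follow the compact two-layer encoder setting (2 transformer
#' layers, hidden size 128); the feed-forward inner size defaults to four
#' times the hidden size.
#'
#' @param n_layers Transformer layers.
#' @param hidden_size Hidden representation size `d`.
#' @param n_heads Attention heads; must divide `hidden_size`.
#' @param ff_size Feed-forward inner size.
#' @param max_tokens Maximum tokens per sentence (including the leading
#'   `[CLS]`); longer sentences are truncated with a warning.
#' @param pooling `"mean"` (over non-special final hidden states, default)
#'   or `"cls"`.
#' @param seed Integer seed for weight initialization.
#' @return An `encoder_config`.
#' @export
encoder_config <- function(n_layers = 2, hidden_size = 128, n_heads = 2,
                           ff_size = 4 * hidden_size, max_tokens = 512,
                           pooling = c("mean", "cls"), seed = 1) {
  pooling <- match.arg(pooling)
  stop_if(hidden_size %% n_heads != 0, "hidden_size must be divisible by n_heads")
  structure(list(n_layers = as.integer(n_layers),
                 hidden_size = as.integer(hidden_size),
                 n_heads = as.integer(n_heads),
                 ff_size = as.integer(ff_size),
                 max_tokens = as.integer(max_tokens),
                 pooling = pooling,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

cfg_ints <- function(cfg, tok) {
  c(vocab_size(tok), cfg$hidden_size, cfg$n_layers, cfg$n_heads,
    cfg$ff_size, cfg$max_tokens)
}

pooling_code <- function(cfg) if (cfg$pooling == "cls") 1L else 0L

#' Initialize an encoder
#'
#' Weights are drawn N(0, 0.02^2), biases start at zero and layer-norm gains
#' at one. Initialization is reproducible from `cfg$seed`.
#'
#' @param cfg An [encoder_config()].
#' @param tokenizer A [whitespace_tokenizer()].
#' @return A `tedi_encoder` holding the flat parameter vector, its config
#'   and tokenizer, and an (initially empty) training history.
#' @export
encoder_init <- function(cfg, tokenizer) {
  stopifnot(inherits(cfg, "encoder_config"),
            inherits(tokenizer, "tedi_tokenizer"))
  ci <- cfg_ints(cfg, tokenizer)
  lay <- cpp_enc_layout(ci)
  theta <- numeric(lay$total)
  off <- cumsum(c(0, lay$lengths))
  local_seed(cfg$seed, {
    for (i in seq_along(lay$names)) {
      rng <- (off[i] + 1):(off[i] + lay$lengths[i])
      nm <- lay$names[i]
      if (grepl("_g$", nm)) {
        theta[rng] <- 1
      } else if (grepl("^b|_b$|_b[qkvo]$", nm) || grepl("b[qkvo12]$", nm)) {
        theta[rng] <- 0
      } else if (grepl("W|emb", nm)) {
        theta[rng] <- rnorm(lay$lengths[i], 0, 0.02)
      }
    }
  })
  structure(list(theta = theta, cfg = cfg, tokenizer = tokenizer,
                 history = NULL),
            class = "tedi_encoder")
}

#' Apply the masked-language-model corruption to a token-id sequence
#'
#' Selects `ceiling(mask_rate * n_eligible)` non-special positions; each is
#' replaced by `[MASK]` with probability 0.8, by a random vocabulary token
#' with probability 0.1, and kept unchanged with probability 0.1. Targets
#' record the original ids. Draws come from the current RNG state, so a
#' fixed seed gives identical corruptions.
#'
#' @param token_ids Integer token ids (1-based, may include specials).
#' @param mask_rate Fraction of eligible tokens to corrupt, in (0, 1).
#' @param tokenizer The tokenizer defining special-token ids.
#' @return List with `ids` (corrupted), `positions` (1-based indices into
#'   `ids`), `targets` (original ids at those positions).
#' @export
mask_tokens <- function(token_ids, mask_rate = 0.15, tokenizer) {
  stop_if(length(token_ids) == 0, "empty token sequence")
  stop_if(mask_rate <= 0 || mask_rate >= 1, "mask_rate must be in (0, 1)")
  eligible <- which(token_ids > tokenizer$n_special)
  if (length(eligible) == 0)
    return(list(ids = token_ids, positions = integer(0), targets = integer(0)))
  n_sel <- ceiling(mask_rate * length(eligible))
  sel <- if (length(eligible) == 1) eligible else
    sort(sample(eligible, n_sel))
  ids <- token_ids
  targets <- token_ids[sel]
  u <- runif(length(sel))
  n_reg <- length(tokenizer$vocab) - tokenizer$n_special
  for (k in seq_along(sel)) {
    if (u[k] < 0.8) {
      ids[sel[k]] <- tokenizer$mask_id
    } else if (u[k] < 0.9) {
      ids[sel[k]] <- tokenizer$n_special + sample.int(n_reg, 1)
    } # else keep original
  }
  list(ids = ids, positions = sel, targets = targets)
}

# Build the 0-based C++ batch from a list of (ids, positions, targets).
mlm_batch_args <- function(batch) {
  list(sents = lapply(batch, function(b) as.integer(b$ids - 1L)),
       tpos = lapply(batch, function(b) as.integer(b$positions - 1L)),
       tids = lapply(batch, function(b) as.integer(b$targets - 1L)))
}

#' Masked-language-model loss of an encoder on a corrupted batch
#'
#' Mean cross-entropy over all masked target positions in the batch.
#'
#' @param encoder A `tedi_encoder`.
#' @param batch List of corruption records as returned by [mask_tokens()]
#'   (each with `ids`, `positions`, `targets`; ids include `[CLS]`).
#' @return Non-negative scalar loss.
#' @export
mlm_loss <- function(encoder, batch) {
  stop_if(length(batch) == 0, "empty batch")
  n_tgt <- sum(vapply(batch, function(b) length(b$positions), 0L))
  stop_if(n_tgt == 0, "batch has no masked target positions")
  a <- mlm_batch_args(batch)
  ci <- cfg_ints(encoder$cfg, encoder$tokenizer)
  cpp_mlm_batch(encoder$theta, ci, a$sents, a$tpos, a$tids, FALSE)$loss
}

# Encode sentences to [CLS]-prefixed id vectors, truncating over-length ones.
prepare_sentence_ids <- function(encoder, sentences) {
  lapply(sentences, function(s) {
    ids <- encode_sentence_ids(encoder$tokenizer, s)
    if (length(ids) > encoder$cfg$max_tokens) {
      warning("sentence truncated to max_tokens = ", encoder$cfg$max_tokens)
      ids <- ids[seq_len(encoder$cfg$max_tokens)]
    }
    ids
  })
}

#' Embed sentences with a frozen encoder
#'
#' Each sentence is tokenized, passed through the encoder, and pooled per
#' the encoder's pooling config (mean over non-special final hidden states
#' by default).
#'
#' @param encoder A `tedi_encoder`.
#' @param sentences Character vector.
#' @return An `n x d` matrix, one row per sentence.
#' @export
embed_sentences <- function(encoder, sentences) {
  stop_if(length(sentences) == 0, "no sentences to embed")
  stop_if(any(!nzchar(trimws(sentences))), "cannot embed an empty sentence")
  idl <- prepare_sentence_ids(encoder, sentences)
  stop_if(any(vapply(idl, length, 0L) < 2), "sentence has no embeddable tokens")
  ci <- cfg_ints(encoder$cfg, encoder$tokenizer)
  cpp_pool_batch(encoder$theta, ci,
                 lapply(idl, function(x) as.integer(x - 1L)),
                 pooling_code(encoder$cfg))
}

#' Embed one sentence
#' @param encoder A `tedi_encoder`.
#' @param sentence A non-empty string.
#' @return Numeric vector of length `d`.
#' @export
embed_sentence <- function(encoder, sentence) {
  as.numeric(embed_sentences(encoder, sentence)[1, ])
}

#' Abstract embedding: the first m sentence embeddings, zero-padded
#'
#' The first `min(n_sentences, m)` sentences are embedded in order into the
#' rows of an `m x d` matrix; remaining rows are exactly zero and the
#' validity mask marks real rows. Sentences beyond `m` are ignored.
#'
#' @param encoder A `tedi_encoder`.
#' @param sentences Character vector of the document's sentences, in order.
#' @param m Number of rows (default 20).
#' @param doc_id Document id carried along.
#' @return An `abstract_embedding` with fields `matrix` (m x d), `mask`
#'   (length-m logical) and `doc_id`.
#' @export
embed_abstract <- function(encoder, sentences, m = 20, doc_id = "") {
  stop_if(m <= 0, "m must be positive")
  stop_if(length(sentences) == 0, "document has no sentences")
  use <- head(sentences, m)
  emb <- embed_sentences(encoder, use)
  d <- encoder$cfg$hidden_size
  mat <- matrix(0, nrow = m, ncol = d)
  mat[seq_len(nrow(emb)), ] <- emb
  structure(list(matrix = mat,
                 mask = seq_len(m) <= length(use),
                 doc_id = doc_id),
            class = "abstract_embedding")
}

# Row-major flattening: sentence blocks are contiguous.
flatten_embedding <- function(ae) as.vector(t(ae$matrix))

#' Parameter checksum of an encoder
#'
#' MD5 of the serialized parameter vector; used to assert that a frozen
#' encoder is untouched by downstream training.
#'
#' @param encoder A `tedi_encoder`.
#' @return Character MD5 digest.
#' @export
enc_checksum <- function(encoder) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(encoder$theta, f, version = 3)
  unname(tools::md5sum(f))
}

#' Save / load encoder checkpoints
#'
#' Checkpoints embed the configuration and tokenizer, so a loaded encoder
#' is immediately usable.
#'
#' @param encoder A `tedi_encoder`.
#' @param path Checkpoint path (RDS container).
#' @return `path` invisibly (save); the encoder (load).
#' @export
save_encoder <- function(encoder, path) {
  saveRDS(encoder, path, version = 3)
  invisible(path)
}

#' @rdname save_encoder
#' @export
load_encoder <- function(path) {
  enc <- readRDS(path)
  stopifnot(inherits(enc, "tedi_encoder") || inherits(enc, "tedi_anchor"))
  enc
}

#' @export
print.tedi_encoder <- function(x, ...) {
  cat("<tedi_encoder> layers:", x$cfg$n_layers,
      " d:", x$cfg$hidden_size,
      " heads:", x$cfg$n_heads,
      " vocab:", vocab_size(x$tokenizer),
      " params:", length(x$theta), "\n")
  invisible(x)
}
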