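# The temporal discriminator (a linear classifier over flattened abstract
# embeddings), the binary cross-entropy adversarial loss, the Frobenius
# anchor loss, and the frozen anchor model. Convention: OLD encodes label 0
# and NEW label 1 (recorded on the discriminator).

#' Construct a temporal discriminator
#'
#' A linear classifier over the flattened `m x d` abstract embedding, with
#' `d * m + 1` parameters (weights plus bias). Weights start at zero, so an
#' untrained discriminator outputs probability 0.5 everywhere.
#'
#' @param m Rows of the abstract embedding.
#' @param d Sentence-embedding width.
#' @return A `temporal_discriminator`.
#' @export
temporal_discriminator <- function(m, d) {
  structure(list(weights = numeric(m * d), bias = 0,
                 m = as.integer(m), d = as.integer(d),
                 label_coding = c(OLD = 0, NEW = 1)),
            class = "temporal_discriminator")
}

#' Discriminator parameter count
#' @param disc A `temporal_discriminator`.
#' @return `d * m + 1`.
#' @export
n_parameters <- function(disc) length(disc$weights) + 1L

#' Probability that an abstract embedding is from the NEW period
#'
#' `sigmoid(weights . flatten(matrix) + bias)`; padded (all-zero) rows
#' contribute nothing to the score.
#'
#' @param disc A `temporal_discriminator`.
#' @param emb An `abstract_embedding` (or an `m x d` matrix).
#' @return Probability in (0, 1).
#' @export
discriminate <- function(disc, emb) {
  x <- if (inherits(emb, "abstract_embedding")) flatten_embedding(emb)
       else as.vector(t(emb))
  stop_if(length(x) != length(disc$weights),
          "embedding shape does not match discriminator size")
  sigmoid(sum(disc$weights * x) + disc$bias)
}

#' Binary cross-entropy adversarial loss
#'
#' Mean binary cross-entropy of discriminator probabilities against period
#' labels (OLD = 0, NEW = 1). Probabilities are clipped to
#' `[1e-7, 1 - 1e-7]` before the log so the loss is always finite.
#'
#' @param probs Numeric vector of probabilities.
#' @param labels Binary vector (0 = OLD, 1 = NEW).
#' @param weights Optional non-negative per-document weights (normalized to
#'   mean 1); used for period re-weighting experiments.
#' @return Non-negative scalar.
#' @export
adversarial_loss <- function(probs, labels, weights = NULL) {
  stop_if(length(probs) == 0, "empty batch")
  stop_if(length(probs) != length(labels), "probs and labels lengths differ")
  stop_if(!all(labels %in% c(0, 1)), "labels must be 0/1")
  p <- clip01(probs)
  ll <- -(labels * log(p) + (1 - labels) * log(1 - p))
  if (!is.null(weights)) ll <- ll * (weights / mean(weights))
  mean(ll)
}

#' Frobenius anchor loss between generator and anchor embeddings
#'
#' The Frobenius norm of the difference of the two `m x d` matrices. Padded
#' rows are zero in both and contribute nothing.
#'
#' @param gen_emb,anc_emb `abstract_embedding`s of the same document with
#'   identical masks.
#' @return Non-negative scalar; zero iff the matrices are equal.
#' @export
anchor_loss <- function(gen_emb, anc_emb) {
  stopifnot(inherits(gen_emb, "abstract_embedding"),
            inherits(anc_emb, "abstract_embedding"))
  stop_if(!identical(dim(gen_emb$matrix), dim(anc_emb$matrix)),
          "embedding shapes differ")
  stop_if(!identical(gen_emb$mask, anc_emb$mask), "embedding masks differ")
  stop_if(!identical(gen_emb$doc_id, anc_emb$doc_id) &&
            nzchar(gen_emb$doc_id) && nzchar(anc_emb$doc_id),
          "embeddings belong to different documents")
  sqrt(sum((gen_emb$matrix - anc_emb$matrix)^2))
}

#' Train the frozen anchor model
#'
#' An encoder of the given architecture trained with masked language
#' modeling only, on all documents regardless of temporal label, then
#' frozen. The anchor regularizes adversarial training so embeddings keep
#' their original semantics.
#'
#' @param corpus A segmented `tedi_corpus`.
#' @param cfg An [encoder_config()].
#' @param epochs Training epochs.
#' @param tokenizer A tokenizer (built from the corpus if omitted).
#' @param lr,batch_size,mask_rate,seed Optimization settings (Adam).
#' @return A `tedi_anchor`: the frozen encoder plus a provenance record.
#' @export
train_anchor <- function(corpus, cfg, epochs, tokenizer = NULL,
                         lr = 2e-5, batch_size = 16, mask_rate = 0.15,
                         seed = 1) {
  stop_if(nrow(corpus) == 0, "empty corpus")
  if (is.null(tokenizer)) tokenizer <- whitespace_tokenizer(build_vocab(corpus$text))
  enc <- train_mlm_baseline(corpus, cfg, epochs = epochs,
                            tokenizer = tokenizer, lr = lr,
                            batch_size = batch_size, mask_rate = mask_rate,
                            seed = seed)
  structure(list(encoder = enc,
                 provenance = list(n_docs = nrow(corpus), epochs = epochs,
                                   lr = lr, seed = seed)),
            class = "tedi_anchor")
}

anchor_encoder <- function(anchor) {
  if (inherits(anchor, "tedi_anchor")) anchor$encoder else anchor
}
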