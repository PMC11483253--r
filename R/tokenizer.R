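# Whitespace tokenizer with a closed, corpus-built vocabulary.
#
# Token ids are 1-based on the R side; the C++ core receives 0-based ids.
# Special tokens occupy the first four ids:
#   [PAD] = 1, [UNK] = 2, [MASK] = 3, [CLS] = 4.
# Every encoded sentence gets a leading [CLS]; mean pooling excludes it.

SPECIAL_TOKENS <- c("[PAD]", "[UNK]", "[MASK]", "[CLS]")

normalize_tokens <- function(text) {
  toks <- strsplit(tolower(text), "\\s+")[[1]]
  toks <- gsub("[.,;:!?]+", "", toks)
  toks[nzchar(toks)]
}

#' Build a vocabulary from raw texts
#'
#' Tokens are lowercased, stripped of punctuation and sorted. Intended for
#' closed synthetic vocabularies; for natural text a subword tokenizer would
#' be plugged in instead.
#'
#' @param texts Character vector of texts.
#' @return Sorted character vector of unique tokens.
#' @export
build_vocab <- function(texts) {
  sort(unique(unlist(lapply(texts, normalize_tokens))))
}

#' Construct a whitespace tokenizer over a fixed vocabulary
#'
#' @param vocab Character vector of (non-special) tokens.
#' @return A `tedi_tokenizer`.
#' @export
whitespace_tokenizer <- function(vocab) {
  stop_if(length(vocab) == 0, "vocabulary must be non-empty")
  stop_if(any(vocab %in% SPECIAL_TOKENS), "vocabulary clashes with special tokens")
  full <- c(SPECIAL_TOKENS, vocab)
  index <- seq_along(full)
  names(index) <- full
  structure(list(vocab = full, index = index,
                 n_special = length(SPECIAL_TOKENS),
                 pad_id = 1L, unk_id = 2L, mask_id = 3L, cls_id = 4L),
            class = "tedi_tokenizer")
}

vocab_size <- function(tok) length(tok$vocab)

# Token ids of a sentence (no [CLS]); out-of-vocabulary tokens map to [UNK].
tokenize_ids <- function(tok, sentence) {
  toks <- normalize_tokens(sentence)
  ids <- unname(tok$index[toks])
  ids[is.na(ids)] <- tok$unk_id
  as.integer(ids)
}

# [CLS]-prefixed ids ready for the encoder.
encode_sentence_ids <- function(tok, sentence) {
  c(tok$cls_id, tokenize_ids(tok, sentence))
}
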