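# Corpus handling: reading JSONL corpora, temporal labeling, sentence
# segmentation and reproducible train/test splitting.
#
# A corpus is a tibble with one document per row:
#   id (character), year (integer), text (character),
#   temporal_label (one of "OLD", "NEW", "UNLABELED"),
#   sentences (list column of character vectors; NULL before segmentation).

TEMPORAL_LEVELS <- c("OLD", "NEW", "UNLABELED")

new_corpus <- function(df) {
  stop_if(anyDuplicated(df$id) > 0, "duplicate document id: ",
          df$id[duplicated(df$id)][1])
  stop_if(any(df$year < 0), "year must be >= 0")
  out <- tibble::tibble(
    id = as.character(df$id),
    year = as.integer(df$year),
    text = as.character(df$text),
    temporal_label = if ("temporal_label" %in% names(df))
      as.character(df$temporal_label) else rep("UNLABELED", nrow(df)),
    sentences = if ("sentences" %in% names(df)) df$sentences
      else vector("list", nrow(df))
  )
  class(out) <- c("tedi_corpus", class(out))
  out
}

#' Read a corpus of timestamped documents from a JSONL file
#'
#' Each line must be a JSON object with fields `id` (string), `year`
#' (integer) and `text` (string). Documents are returned in file order with
#' temporal label `UNLABELED`.
#'
#' @param path Path to a JSONL file.
#' @return A corpus tibble (class `tedi_corpus`) with columns `id`, `year`,
#'   `text`, `temporal_label` and a `sentences` list column.
#' @export
read_corpus <- function(path) {
  stop_if(!file.exists(path), "corpus file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(new_corpus(
    data.frame(id = character(), year = integer(), text = character())))
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("malformed JSON on line ", i,
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    for (f in c("id", "year", "text"))
      stop_if(is.null(obj[[f]]), "line ", i, ": missing field '", f, "'")
    list(id = as.character(obj$id), year = as.integer(obj$year),
         text = as.character(obj$text))
  })
  new_corpus(data.frame(
    id = vapply(recs, `[[`, "", "id"),
    year = vapply(recs, `[[`, 0L, "year"),
    text = vapply(recs, `[[`, "", "text"),
    stringsAsFactors = FALSE
  ))
}

#' Write a corpus to JSONL
#'
#' @param corpus A `tedi_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(id = corpus$id[i],
                                     year = corpus$year[i],
                                     text = corpus$text[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Configuration of the old/new period split
#'
#' Two disjoint inclusive year ranges define the OLD and NEW periods; years
#' in the gap between them (or outside both) stay unlabeled. The default
#' ranges are old 2010-2013 and new 2016-2018, leaving 2014-2015 as the gap
#' that makes the periods distinguishable.
#'
#' @param old_years,new_years Integer vectors of consecutive years.
#' @return A `temporal_split_config` object.
#' @export
temporal_split_config <- function(old_years = 2010:2013,
                                  new_years = 2016:2018) {
  old_years <- as.integer(old_years); new_years <- as.integer(new_years)
  stop_if(length(old_years) == 0 || length(new_years) == 0,
          "year ranges must be non-empty")
  stop_if(length(intersect(old_years, new_years)) > 0,
          "old and new year ranges must be disjoint")
  stop_if(max(old_years) >= min(new_years),
          "the old range must precede the new range")
  structure(list(old_years = old_years, new_years = new_years),
            class = "temporal_split_config")
}

#' Assign temporal labels to documents
#'
#' Labels each document OLD or NEW according to its year and the configured
#' ranges; documents in the gap or outside both ranges are marked UNLABELED
#' and retained. Labeling is total and idempotent.
#'
#' @param corpus A `tedi_corpus`.
#' @param cfg A [temporal_split_config()].
#' @return The corpus with `temporal_label` filled in.
#' @export
assign_temporal_labels <- function(corpus, cfg = temporal_split_config()) {
  stopifnot(inherits(cfg, "temporal_split_config"))
  lab <- rep("UNLABELED", nrow(corpus))
  lab[corpus$year %in% cfg$old_years] <- "OLD"
  lab[corpus$year %in% cfg$new_years] <- "NEW"
  corpus$temporal_label <- lab
  corpus
}

# Punctuation-based sentence boundary detection: split on runs of
# sentence-final punctuation followed by whitespace.
split_sentences <- function(text) {
  stop_if(!nzchar(trimws(text)), "cannot segment an empty text")
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  parts
}

#' Segment corpus documents into sentences
#'
#' Populates the `sentences` list column using a deterministic
#' punctuation-based boundary detector (split after `.`, `!` or `?`
#' followed by whitespace). The segmenter identity is recorded in the
#' `segmenter` attribute of the result.
#'
#' @param corpus A `tedi_corpus` with non-empty `text` fields.
#' @return The corpus with `sentences` populated.
#' @export
segment_sentences <- function(corpus) {
  corpus$sentences <- lapply(corpus$text, split_sentences)
  attr(corpus, "segmenter") <- "tedi::split_sentences (regex punctuation)"
  corpus
}

#' Reproducible train/test split of a corpus
#'
#' @param corpus A `tedi_corpus` with at least 2 documents.
#' @param train_fraction Fraction of documents assigned to the train set;
#'   `round(train_fraction * N)` documents are selected.
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A `corpus_split` list with `train` and `test` id vectors and the
#'   seed.
#' @export
split_train_test <- function(corpus, train_fraction, seed) {
  stop_if(nrow(corpus) < 2, "need at least 2 documents to split")
  stop_if(!is.numeric(train_fraction) || train_fraction <= 0 ||
          train_fraction >= 1, "train_fraction must be in (0, 1)")
  n <- nrow(corpus)
  n_train <- round(train_fraction * n)
  idx <- local_seed(seed, sample.int(n, n_train))
  structure(list(train = corpus$id[sort(idx)],
                 test = corpus$id[sort(setdiff(seq_len(n), idx))],
                 seed = as.integer(seed)),
            class = "corpus_split")
}

corpus_subset <- function(corpus, ids) {
  corpus[match(ids, corpus$id), , drop = FALSE]
}
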