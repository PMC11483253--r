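# Synthetic data generation: temporal-drift corpora from a topic-mixture
# process with period-interpolated word tables, planted concept pairs whose
# sentence co-occurrence rate differs between periods, and code-sequence
# patient records with group-dependent outcome signal.

#' Configuration for the temporal-drift corpus generator
#'
#' Documents are produced by a topic mixture: each document draws a topic
#' distribution, each sentence draws a topic and its tokens are sampled from
#' the topic's word table. A designated fraction of words "drifts": for new-
#' period documents their topic-word probabilities are interpolated between
#' an old table and an independent new table with weight `drift_strength`
#' (delta). `delta = 0` yields exchangeable old and new documents; larger
#' delta makes the periods increasingly separable from token counts alone.
#'
#' @param vocab_size Number of word types (excluding special tokens).
#' @param n_docs_old,n_docs_new Documents per period.
#' @param sentences_per_doc,tokens_per_sentence Integer `(min, max)` ranges.
#' @param n_topics Number of latent topics.
#' @param drift_strength Interpolation weight delta in `[0, 1]`.
#' @param drifting_word_fraction Fraction of the vocabulary whose topic-word
#'   probabilities differ between the period tables.
#' @param old_years,new_years Calendar-year ranges used to stamp documents.
#' @param pair_injection_rate Per-sentence probability of injecting a planted
#'   concept pair (only used when pairs are supplied to the generator).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `drift_corpus_config`.
#' @export
drift_corpus_config <- function(vocab_size = 500,
                                n_docs_old = 1000, n_docs_new = 1000,
                                sentences_per_doc = c(3, 8),
                                tokens_per_sentence = c(5, 12),
                                n_topics = 8,
                                drift_strength = 0.8,
                                drifting_word_fraction = 0.2,
                                old_years = 2010:2013,
                                new_years = 2016:2018,
                                pair_injection_rate = 0.3,
                                seed = 1) {
  stop_if(drift_strength < 0 || drift_strength > 1,
          "drift_strength must be in [0, 1]")
  stop_if(drifting_word_fraction < 0 || drifting_word_fraction > 1,
          "drifting_word_fraction must be in [0, 1]")
  stop_if(vocab_size < n_topics, "vocab_size must be >= n_topics")
  structure(list(vocab_size = as.integer(vocab_size),
                 n_docs_old = as.integer(n_docs_old),
                 n_docs_new = as.integer(n_docs_new),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 tokens_per_sentence = as.integer(tokens_per_sentence),
                 n_topics = as.integer(n_topics),
                 drift_strength = drift_strength,
                 drifting_word_fraction = drifting_word_fraction,
                 old_years = as.integer(old_years),
                 new_years = as.integer(new_years),
                 pair_injection_rate = pair_injection_rate,
                 seed = as.integer(seed)),
            class = "drift_corpus_config")
}

# Word strings: w001 ... wNNN; concept tokens are reserved from the top of
# the vocabulary and named cNNNa / cNNNb so they are recognizable.
word_strings <- function(n) sprintf("w%03d", seq_len(n))

#' Generate planted concept pairs
#'
#' Reserves `2 * n_pairs` tokens from the top of the configured vocabulary
#' and assigns each pair a per-period relatedness in (0, 1). Relatedness is
#' operationalized by the corpus generator as the probability that the two
#' concepts of a pair co-occur in the same sentence when the pair is
#' injected. Both period rankings are strict (no ties) by construction, and
#' old and new relatedness never coincide, so every pair drifts.
#'
#' @param cfg A [drift_corpus_config()].
#' @param n_pairs Number of concept pairs.
#' @return A tibble with `pair_id`, `concept_a`, `concept_b`,
#'   `relatedness_old`, `relatedness_new`.
#' @export
generate_concept_pairs <- function(cfg, n_pairs) {
  stop_if(2L * n_pairs >= cfg$vocab_size,
          "vocabulary too small to reserve ", 2L * n_pairs, " concept tokens")
  ids <- seq_len(n_pairs)
  local_seed(cfg$seed + 77L, {
    rel_old <- sample(seq(0.08, 0.92, length.out = n_pairs))
    rel_new <- sample(seq(0.10, 0.94, length.out = n_pairs))
  })
  tibble::tibble(
    pair_id = sprintf("pair%02d", ids),
    concept_a = sprintf("c%02da", ids),
    concept_b = sprintf("c%02db", ids),
    relatedness_old = rel_old,
    relatedness_new = rel_new
  )
}

# Vocabulary used by a drift corpus: regular words plus reserved concept
# tokens (which replace the top 2*n_pairs regular words when pairs exist).
drift_vocab <- function(cfg, pairs = NULL) {
  n_res <- if (is.null(pairs)) 0L else 2L * nrow(pairs)
  reg <- word_strings(cfg$vocab_size - n_res)
  if (n_res == 0) return(reg)
  c(reg, as.vector(rbind(pairs$concept_a, pairs$concept_b)))
}

#' Generate a temporal-drift corpus
#'
#' See [drift_corpus_config()] for the generative process. When `pairs` are
#' supplied, each sentence is, with probability `pair_injection_rate`,
#' augmented with a planted pair: both concepts are inserted with
#' probability equal to the pair's period relatedness, otherwise a single
#' randomly chosen concept of the pair is inserted. Sentence-level
#' co-occurrence counts therefore track the per-period relatedness.
#'
#' @param cfg A [drift_corpus_config()].
#' @param pairs Optional tibble from [generate_concept_pairs()].
#' @return A labeled, sentence-segmented `tedi_corpus`.
#' @export
generate_drift_corpus <- function(cfg, pairs = NULL) {
  stopifnot(inherits(cfg, "drift_corpus_config"))
  n_res <- if (is.null(pairs)) 0L else 2L * nrow(pairs)
  n_reg <- cfg$vocab_size - n_res
  stop_if(n_reg < cfg$n_topics, "vocabulary too small after reserving concepts")
  words <- word_strings(n_reg)
  K <- cfg$n_topics
  delta <- cfg$drift_strength

  local_seed(cfg$seed, {
    # topic-word tables: shared gamma weights; drifting words get fresh
    # weights in the "new" table, then both tables are normalized.
    n_drift <- floor(cfg$drifting_word_fraction * n_reg)
    drift_idx <- if (n_drift > 0) sample.int(n_reg, n_drift) else integer(0)
    g_old <- matrix(rgamma(K * n_reg, shape = 0.1), K, n_reg)
    g_new <- g_old
    if (n_drift > 0)
      g_new[, drift_idx] <- matrix(rgamma(K * n_drift, shape = 0.1), K, n_drift)
    phi_old <- g_old / rowSums(g_old)
    phi_new_full <- g_new / rowSums(g_new)
    # new-period table: interpolation with weight delta
    phi_new <- (1 - delta) * phi_old + delta * phi_new_full

    n_docs <- cfg$n_docs_old + cfg$n_docs_new
    period <- rep(c("OLD", "NEW"), c(cfg$n_docs_old, cfg$n_docs_new))
    years <- c(sample(cfg$old_years, cfg$n_docs_old, replace = TRUE),
               sample(cfg$new_years, cfg$n_docs_new, replace = TRUE))
    texts <- character(n_docs)
    for (i in seq_len(n_docs)) {
      phi <- if (period[i] == "OLD") phi_old else phi_new
      theta <- rgamma(K, shape = 0.5)
      theta <- theta / sum(theta)
      n_sent <- sample(cfg$sentences_per_doc[1]:cfg$sentences_per_doc[2], 1)
      sents <- character(n_sent)
      for (s in seq_len(n_sent)) {
        z <- sample.int(K, 1, prob = theta)
        n_tok <- sample(cfg$tokens_per_sentence[1]:cfg$tokens_per_sentence[2], 1)
        toks <- words[sample.int(n_reg, n_tok, replace = TRUE, prob = phi[z, ])]
        if (!is.null(pairs) && runif(1) < cfg$pair_injection_rate) {
          j <- sample.int(nrow(pairs), 1)
          rel <- if (period[i] == "OLD") pairs$relatedness_old[j]
                 else pairs$relatedness_new[j]
          ins <- if (runif(1) < rel) c(pairs$concept_a[j], pairs$concept_b[j])
                 else sample(c(pairs$concept_a[j], pairs$concept_b[j]), 1)
          toks <- sample(c(toks, ins))
        }
        sents[s] <- paste0(paste(toks, collapse = " "), ".")
      }
      texts[i] <- paste(sents, collapse = " ")
    }
  })

  corpus <- new_corpus(data.frame(id = sprintf("doc%05d", seq_along(texts)),
                                  year = years, text = texts,
                                  stringsAsFactors = FALSE))
  corpus <- assign_temporal_labels(
    corpus, temporal_split_config(cfg$old_years, cfg$new_years))
  segment_sentences(corpus)
}

#' Configuration for synthetic patient records
#'
#' Patients carry a group label (female/male, the female share defaulting to
#' the ~44% imbalance typical of large ICU cohorts), an age, three ordered
#' sequences of code descriptions (previous diagnoses, current diagnoses,
#' medications) and an outcome driven by a linear predictor over planted
#' code-presence effects plus a group-dependent interaction.
#'
#' @param n_patients Number of patients.
#' @param female_fraction Probability of the "female" group label.
#' @param code_vocab Character vector of code-description strings.
#' @param sequence_length Integer `(min, max)` codes per sequence.
#' @param outcome_kind `"BINARY"` (Bernoulli via logistic link) or
#'   `"CONTINUOUS"` (Gaussian noise around the linear predictor).
#' @param coefficient_map Named numeric vector of per-code effects (names
#'   must be a subset of `code_vocab`).
#' @param group_interaction Effect added when a female patient carries at
#'   least one nonzero-coefficient code.
#' @param intercept Linear-predictor intercept.
#' @param noise_sd Gaussian noise SD for continuous outcomes.
#' @param seed Integer seed.
#' @return A `synthetic_patient_config`.
#' @export
synthetic_patient_config <- function(n_patients = 1000,
                                     female_fraction = 0.44,
                                     code_vocab,
                                     sequence_length = c(3, 8),
                                     outcome_kind = c("BINARY", "CONTINUOUS"),
                                     coefficient_map = numeric(0),
                                     group_interaction = 0,
                                     intercept = 0,
                                     noise_sd = 1,
                                     seed = 1) {
  outcome_kind <- match.arg(outcome_kind)
  stop_if(missing(code_vocab) || length(code_vocab) == 0,
          "code_vocab must be non-empty")
  stop_if(female_fraction <= 0 || female_fraction >= 1,
          "female_fraction must be in (0, 1)")
  stop_if(length(coefficient_map) > 0 &&
            !all(names(coefficient_map) %in% code_vocab),
          "coefficient_map names must be a subset of code_vocab")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 female_fraction = female_fraction,
                 code_vocab = as.character(code_vocab),
                 sequence_length = as.integer(sequence_length),
                 outcome_kind = outcome_kind,
                 coefficient_map = coefficient_map,
                 group_interaction = group_interaction,
                 intercept = intercept,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_patient_config")
}

#' Build a code vocabulary of multi-word descriptions
#'
#' Composes `n_codes` distinct descriptions from a pool of word tokens, so
#' that code descriptions are embeddable by an encoder trained on a corpus
#' over the same tokens.
#'
#' @param tokens Word pool (e.g. the corpus vocabulary).
#' @param n_codes Number of codes.
#' @param words_per_code Words per description.
#' @param seed Integer seed.
#' @return Character vector of descriptions.
#' @export
make_code_vocab <- function(tokens, n_codes, words_per_code = 3, seed = 1) {
  stop_if(length(tokens) < words_per_code, "token pool too small")
  local_seed(seed, {
    vapply(seq_len(n_codes), function(i)
      paste(sample(tokens, words_per_code), collapse = " "), character(1))
  })
}

#' Generate synthetic patient records
#'
#' The linear predictor is
#' `intercept + sum(coefficient_map[codes present]) +
#'  group_interaction * I(female) * I(any nonzero-coefficient code present)`;
#' presence means the code appears in any of the patient's three sequences.
#' Continuous outcomes add Gaussian noise; binary outcomes are Bernoulli
#' draws through the logistic link.
#'
#' @param cfg A [synthetic_patient_config()].
#' @return A tibble with one patient per row: `patient_id`, `group`, `age`,
#'   list columns `prev_diagnoses`, `curr_diagnoses`, `medications`, and
#'   `outcome`. The `primary_diagnosis` column holds the first current
#'   diagnosis.
#' @export
generate_patients <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_patient_config"))
  n <- cfg$n_patients
  C <- length(cfg$code_vocab)
  signal_codes <- names(cfg$coefficient_map)[cfg$coefficient_map != 0]
  local_seed(cfg$seed, {
    n_f <- round(cfg$female_fraction * n)
    group <- sample(rep(c("F", "M"), c(n_f, n - n_f)))
    age <- round(pmax(18, pmin(95, rnorm(n, 62, 15))))
    draw_seq <- function() {
      len <- sample(cfg$sequence_length[1]:cfg$sequence_length[2], 1)
      cfg$code_vocab[sample.int(C, len, replace = TRUE)]
    }
    prev <- replicate(n, draw_seq(), simplify = FALSE)
    curr <- replicate(n, draw_seq(), simplify = FALSE)
    meds <- replicate(n, draw_seq(), simplify = FALSE)
    lp <- numeric(n)
    for (i in seq_len(n)) {
      present <- unique(c(prev[[i]], curr[[i]], meds[[i]]))
      lp[i] <- cfg$intercept +
        sum(cfg$coefficient_map[intersect(names(cfg$coefficient_map), present)]) +
        cfg$group_interaction * (group[i] == "F") *
          (length(intersect(signal_codes, present)) > 0)
    }
    outcome <- if (cfg$outcome_kind == "CONTINUOUS") {
      lp + rnorm(n, 0, cfg$noise_sd)
    } else {
      as.integer(runif(n) < plogis(lp))
    }
  })
  out <- tibble::tibble(
    patient_id = sprintf("pt%05d", seq_len(n)),
    group = group, age = as.numeric(age),
    prev_diagnoses = prev, curr_diagnoses = curr, medications = meds,
    primary_diagnosis = vapply(curr, `[`, "", 1),
    outcome = outcome
  )
  class(out) <- c("tedi_patients", class(out))
  out
}

#' Write concept pairs to CSV
#' @param pairs Tibble from [generate_concept_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' Write patient records to JSONL
#' @param patients Tibble from [generate_patients()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patients_jsonl <- function(patients, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(patients))) {
    writeLines(jsonlite::toJSON(list(
      patient_id = patients$patient_id[i],
      group = patients$group[i],
      age = patients$age[i],
      prev_diagnoses = patients$prev_diagnoses[[i]],
      curr_diagnoses = patients$curr_diagnoses[[i]],
      medications = patients$medications[[i]],
      outcome = patients$outcome[i]), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read patient records from JSONL
#' @param path Path written by [write_patients_jsonl()].
#' @return A `tedi_patients` tibble.
#' @export
read_patients_jsonl <- function(path) {
  stop_if(!file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- tibble::tibble(
    patient_id = vapply(recs, `[[`, "", "patient_id"),
    group = vapply(recs, `[[`, "", "group"),
    age = vapply(recs, `[[`, 0, "age"),
    prev_diagnoses = lapply(recs, `[[`, "prev_diagnoses"),
    curr_diagnoses = lapply(recs, `[[`, "curr_diagnoses"),
    medications = lapply(recs, `[[`, "medications"),
    outcome = vapply(recs, `[[`, 0, "outcome")
  )
  out$primary_diagnosis <- vapply(out$curr_diagnoses, `[`, "", 1)
  class(out) <- c("tedi_patients", class(out))
  out
}
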