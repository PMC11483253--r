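test_that("generation is byte-identical for identical configs and seeds", {
  cfg <- drift_corpus_config(vocab_size = 60, n_docs_old = 20, n_docs_new = 20,
                             n_topics = 4, seed = 9)
  pairs <- generate_concept_pairs(cfg, 5)
  expect_identical(generate_drift_corpus(cfg, pairs),
                   generate_drift_corpus(cfg, pairs))
  pcfg <- synthetic_patient_config(n_patients = 50,
                                   code_vocab = letters[1:10], seed = 4)
  expect_identical(generate_patients(pcfg), generate_patients(pcfg))
})

test_that("drift corpus has the configured composition", {
  corp <- small_corpus(25, 35)
  expect_equal(nrow(corp), 60)
  expect_equal(sum(corp$temporal_label == "OLD"), 25)
  expect_equal(sum(corp$temporal_label == "NEW"), 35)
  expect_true(all(corp$year[corp$temporal_label == "OLD"] %in% 2010:2013))
  expect_true(all(corp$year[corp$temporal_label == "NEW"] %in% 2016:2018))
  ns <- lengths(corp$sentences)
  expect_true(all(ns >= 3 & ns <= 8))
})

test_that("delta = 0 gives exchangeable periods; separability grows with delta", {
  accs <- vapply(c(0, 0.4, 0.8), function(delta) {
    cfg <- drift_corpus_config(vocab_size = 200, n_docs_old = 200,
                               n_docs_new = 200, drift_strength = delta,
                               seed = 31)
    oracle_period_accuracy(generate_drift_corpus(cfg), seed = 1)
  }, numeric(1))
  # chance level at delta = 0, within Monte-Carlo error of a 120-doc test set
  expect_lt(accs[1], 0.62)
  # monotone in delta, with Monte-Carlo slack
  expect_gt(accs[2], accs[1] - 0.05)
  expect_gt(accs[3], accs[2] - 0.05)
  # strong drift is clearly separable
  expect_gt(accs[3], 0.75)
})

test_that("concept pairs reserve vocabulary and plant strict drifting rankings", {
  cfg <- drift_corpus_config(vocab_size = 120, n_docs_old = 150,
                             n_docs_new = 150, seed = 17)
  pairs <- generate_concept_pairs(cfg, 20)
  expect_equal(nrow(pairs), 20)
  # 40 concept mentions reserved within the 120-token vocabulary
  voc <- tedi:::drift_vocab(cfg, pairs)
  expect_length(voc, 120)
  expect_true(all(c(pairs$concept_a, pairs$concept_b) %in% voc))
  # strict rankings, every pair drifts
  expect_false(anyDuplicated(pairs$relatedness_old) > 0)
  expect_false(anyDuplicated(pairs$relatedness_new) > 0)
  expect_true(all(pairs$relatedness_old != pairs$relatedness_new))
  expect_error(generate_concept_pairs(cfg, 60), "too small")
})

test_that("sentence co-occurrence tracks planted per-period relatedness", {
  cfg <- drift_corpus_config(vocab_size = 120, n_docs_old = 400,
                             n_docs_new = 400, pair_injection_rate = 0.5,
                             seed = 23)
  pairs <- generate_concept_pairs(cfg, 6)
  corp <- generate_drift_corpus(cfg, pairs)
  # oracle: count same-sentence co-occurrences directly in the corpus
  cooc_rate <- function(corpus, a, b) {
    sents <- unlist(corpus$sentences)
    has_a <- grepl(paste0("\\b", a, "\\b"), sents)
    has_b <- grepl(paste0("\\b", b, "\\b"), sents)
    sum(has_a & has_b) / max(1, sum(has_a | has_b))
  }
  new_corp <- corp[corp$temporal_label == "NEW", ]
  hi <- which.max(pairs$relatedness_new)
  lo <- which.min(pairs$relatedness_new)
  r_hi <- cooc_rate(new_corp, pairs$concept_a[hi], pairs$concept_b[hi])
  r_lo <- cooc_rate(new_corp, pairs$concept_a[lo], pairs$concept_b[lo])
  expect_gt(r_hi, r_lo)
})

test_that("patient outcomes follow the planted linear predictor", {
  codes <- sprintf("code %02d", 1:12)
  # zero effects, zero noise, continuous -> outcome is exactly the intercept
  cfg0 <- synthetic_patient_config(n_patients = 40, code_vocab = codes,
                                   outcome_kind = "CONTINUOUS",
                                   intercept = 2.5, noise_sd = 0, seed = 1)
  expect_true(all(generate_patients(cfg0)$outcome == 2.5))

  # group allocation is exact up to rounding
  cfgF <- synthetic_patient_config(n_patients = 1000, female_fraction = 0.44,
                                   code_vocab = codes, seed = 2)
  expect_equal(sum(generate_patients(cfgF)$group == "F"), 440)

  # a strong positive coefficient raises the outcome rate among carriers
  cfgB <- synthetic_patient_config(
    n_patients = 800, code_vocab = codes, outcome_kind = "BINARY",
    coefficient_map = c("code 01" = 3), intercept = -1.5, seed = 3)
  pts <- generate_patients(cfgB)
  carrier <- vapply(seq_len(nrow(pts)), function(i)
    "code 01" %in% c(pts$prev_diagnoses[[i]], pts$curr_diagnoses[[i]],
                     pts$medications[[i]]), logical(1))
  expect_gt(mean(pts$outcome[carrier]), mean(pts$outcome[!carrier]))

  expect_error(synthetic_patient_config(n_patients = 10,
                                        code_vocab = character(0)),
               "non-empty")
})

test_that("ordinary least squares recovers planted continuous effects", {
  codes <- sprintf("code %02d", 1:15)
  beta <- c("code 01" = 1.5, "code 02" = -1, "code 03" = 0.5)
  cfg <- synthetic_patient_config(n_patients = 2000, code_vocab = codes,
                                  outcome_kind = "CONTINUOUS",
                                  coefficient_map = beta, intercept = 1,
                                  noise_sd = 1, seed = 11)
  pts <- generate_patients(cfg)
  X <- vapply(codes, function(cd) vapply(seq_len(nrow(pts)), function(i)
    as.numeric(cd %in% c(pts$prev_diagnoses[[i]], pts$curr_diagnoses[[i]],
                         pts$medications[[i]])), numeric(1)), numeric(nrow(pts)))
  fit <- summary(stats::lm(pts$outcome ~ X))
  est <- coef(fit)[paste0("Xcode ", c("01", "02", "03")), ]
  expect_true(all(abs(est[, "Estimate"] - beta) < 3 * est[, "Std. Error"]))
})

test_that("patients and pairs round-trip through their file formats", {
  codes <- sprintf("code %02d", 1:6)
  pts <- generate_patients(synthetic_patient_config(
    n_patients = 12, code_vocab = codes, seed = 5))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_patients_jsonl(pts, f)
  back <- read_patients_jsonl(f)
  expect_equal(back$patient_id, pts$patient_id)
  expect_equal(back$outcome, as.numeric(pts$outcome))
  expect_identical(back$prev_diagnoses, pts$prev_diagnoses)

  cfg <- drift_corpus_config(vocab_size = 60, seed = 1)
  pairs <- generate_concept_pairs(cfg, 4)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_pairs_csv(pairs, fp)
  expect_equal(utils::read.csv(fp)$concept_a, pairs$concept_a)
})
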