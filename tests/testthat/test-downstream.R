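# Downstream head: gradient correctness, representation contracts,
# frozen-encoder guarantee, group-wise evaluation.

ds_fixture <- function(n = 30, task = "classification", seed = 5) {
  enc <- tiny_encoder(n_vocab = 20, d = 8, seed = 2)
  codes <- make_code_vocab(tiny_vocab(20), n_codes = 10, seed = 3)
  cfg <- synthetic_patient_config(
    n_patients = n, code_vocab = codes,
    outcome_kind = if (task == "classification") "BINARY" else "CONTINUOUS",
    coefficient_map = stats::setNames(c(2, -1), codes[1:2]),
    intercept = if (task == "classification") -0.5 else 1,
    noise_sd = 0.5, seed = seed)
  list(enc = enc, codes = codes, pts = generate_patients(cfg))
}

test_that("head gradients match finite differences", {
  fx <- ds_fixture(n = 6)
  cfg <- head_config("classification", lstm_hidden = 5, mlp_hidden = 4,
                     epochs = 0, seed = 7)
  head <- train_outcome_head(fx$enc, fx$pts, cfg)
  cache <- tedi:::code_cache_for(head, fx$enc, fx$pts)
  y <- fx$pts$outcome
  g <- tedi:::head_grad_vec(head, cache, fx$pts, y)
  theta <- tedi:::head_param_vec(head)
  idx <- withr::with_seed(1, sample(length(theta), 60))
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    hp <- tedi:::head_set_params(head, replace(theta, i, theta[i] + eps))
    hm <- tedi:::head_set_params(head, replace(theta, i, theta[i] - eps))
    (tedi:::head_grad_vec(hp, cache, fx$pts, y)$loss -
     tedi:::head_grad_vec(hm, cache, fx$pts, y)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(num - g$grad[idx]) / pmax(1, abs(num))), 1e-4)

  # regression path too
  fxr <- ds_fixture(n = 6, task = "regression")
  cfgr <- head_config("regression", lstm_hidden = 5, mlp_hidden = 4,
                      epochs = 0, seed = 7)
  headr <- train_outcome_head(fxr$enc, fxr$pts, cfgr)
  cacher <- tedi:::code_cache_for(headr, fxr$enc, fxr$pts)
  yr <- fxr$pts$outcome
  gr <- tedi:::head_grad_vec(headr, cacher, fxr$pts, yr)
  thetar <- tedi:::head_param_vec(headr)
  idxr <- withr::with_seed(2, sample(length(thetar), 40))
  numr <- vapply(idxr, function(i) {
    hp <- tedi:::head_set_params(headr, replace(thetar, i, thetar[i] + eps))
    hm <- tedi:::head_set_params(headr, replace(thetar, i, thetar[i] - eps))
    (tedi:::head_grad_vec(hp, cacher, fxr$pts, yr)$loss -
     tedi:::head_grad_vec(hm, cacher, fxr$pts, yr)$loss) / (2 * eps)
  }, numeric(1))
  expect_lt(max(abs(numr - gr$grad[idxr]) / pmax(1, abs(numr))), 1e-4)
})

test_that("a length-1 sequence equals one LSTM step from the initial state", {
  h <- 4
  par <- withr::with_seed(3, tedi:::lstm_params(6, h))
  x <- withr::with_seed(4, rnorm(6))
  out <- tedi:::lstm_forward(par, list(matrix(x, 1, 6)), h)$out
  pre <- as.vector(x %*% par$Wx) + par$b  # h_prev = 0
  i <- plogis(pre[1:h]); f <- plogis(pre[(h + 1):(2 * h)])
  g <- tanh(pre[(2 * h + 1):(3 * h)]); o <- plogis(pre[(3 * h + 1):(4 * h)])
  expect_equal(as.numeric(out), o * tanh(i * g))
})

test_that("representation length follows the configuration", {
  fx <- ds_fixture(n = 5)
  cfg <- head_config("classification", lstm_hidden = 6, mlp_hidden = 4,
                     epochs = 0, seed = 1)
  head <- train_outcome_head(fx$enc, fx$pts, cfg)
  rep1 <- build_patient_representation(fx$enc, fx$pts[1, ], head)
  expect_length(rep1, 3 * 6 + 2)  # 3 sequences * hidden + age + group

  cfgr <- head_config("regression", lstm_hidden = 6, mlp_hidden = 4,
                      epochs = 0, seed = 1)
  fxr <- ds_fixture(n = 5, task = "regression")
  headr <- train_outcome_head(fxr$enc, fxr$pts, cfgr)
  repr <- build_patient_representation(fxr$enc, fxr$pts[1, ], headr)
  expect_length(repr, 1 * 6 + 8 + 2)  # 1 sequence + primary-diagnosis d + static

  # identical records give identical representations
  expect_identical(build_patient_representation(fx$enc, fx$pts[1, ], head),
                   build_patient_representation(fx$enc, fx$pts[1, ], head))
})

test_that("the encoder is untouched by head training", {
  fx <- ds_fixture(n = 20)
  before <- enc_checksum(fx$enc)
  cfg <- head_config("classification", lstm_hidden = 4, mlp_hidden = 4,
                     epochs = 1, lr = 1e-3, seed = 2)
  head <- train_outcome_head(fx$enc, fx$pts, cfg)
  expect_identical(enc_checksum(fx$enc), before)
  expect_identical(head$encoder_checksum, before)
})

test_that("a constant continuous outcome is fit to near zero loss", {
  fx <- ds_fixture(n = 20, task = "regression")
  fx$pts$outcome <- rep(3, 20)
  cfg <- head_config("regression", lstm_hidden = 4, mlp_hidden = 4,
                     epochs = 250, lr = 2e-2, seed = 2)
  head <- train_outcome_head(fx$enc, fx$pts, cfg)
  preds <- predict_head(head, fx$enc, fx$pts)
  expect_lt(max(abs(preds - 3)), 0.25)
  expect_lt(head$history[length(head$history)], 0.05)
})

test_that("task/outcome mismatches are rejected", {
  fx <- ds_fixture(n = 10, task = "regression")
  cfg <- head_config("classification", epochs = 0, seed = 1)
  expect_error(train_outcome_head(fx$enc, fx$pts, cfg), "0/1")
})

test_that("group-wise evaluation reports CIs, gaps and decomposes MAE", {
  fx <- ds_fixture(n = 40, task = "regression", seed = 9)
  cfg <- head_config("regression", lstm_hidden = 4, mlp_hidden = 4,
                     epochs = 2, lr = 1e-2, seed = 2)
  head <- train_outcome_head(fx$enc, fx$pts, cfg)
  rep <- evaluate_by_group(head, fx$enc, fx$pts, n_resamples = 200, seed = 3)
  expect_equal(rep$metric_name, "mae")
  expect_named(rep$groups, c("F", "M"))
  expect_true(rep$overall$lo <= rep$overall$point &&
                rep$overall$point <= rep$overall$hi)
  # overall MAE is the record-count-weighted mean of group MAEs
  nF <- rep$groups$F$n; nM <- rep$groups$M$n
  expect_equal(rep$overall$point,
               (nF * rep$groups$F$point + nM * rep$groups$M$point) / (nF + nM))
  expect_equal(rep$gaps[["F-M"]], rep$groups$F$point - rep$groups$M$point)
  expect_error(evaluate_by_group(head, fx$enc, fx$pts, group_field = "nope"),
               "unknown group field")

  # a single group: the overall metric equals that group's metric
  one <- fx$pts[fx$pts$group == "F", ]
  rep1 <- evaluate_by_group(head, fx$enc, one, n_resamples = 100, seed = 4)
  expect_equal(rep1$overall$point, rep1$groups$F$point)
})

test_that("perfect scores give AUC 1 in every group", {
  # oracle head: inject scores equal to labels through the AUC path
  y <- c(0, 1, 0, 1, 1, 0)
  expect_equal(auc(y, y), 1)
  g <- c("F", "F", "F", "M", "M", "M")
  for (gr in c("F", "M")) expect_equal(auc(y[g == gr], y[g == gr]), 1)
})
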