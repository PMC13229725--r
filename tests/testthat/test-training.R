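test_that("a small model overfits a tiny separable task to accuracy 1", {
  spec <- tiny_spec(n_per_class = 3, motif_amplitude = 5, seed = 23)
  d <- generate_dataset(spec)                # 9 samples, strong signal
  cfg <- tiny_config(epochs = 120, batch_size = 3, attn_dim = 4,
                     head_hidden = 8, learning_rate = 5e-3, seed = 5)
  fit <- attnseq_fit(d, cfg)
  preds <- predict(fit, d, use_ema = FALSE)
  labs <- vapply(d$samples, function(s) s$label, integer(1))
  expect_equal(mean(preds == labs), 1.0)
})

test_that("training is deterministic under a fixed seed", {
  d <- generate_dataset(tiny_spec(seed = 29))
  cfg <- tiny_config(epochs = 4, dropout = 0.3, seed = 11)
  f1 <- attnseq_fit(d, cfg)
  f2 <- attnseq_fit(d, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(attnseq:::param_flatten(f1$params),
                   attnseq:::param_flatten(f2$params))
  expect_identical(attnseq:::param_flatten(f1$ema_params),
                   attnseq:::param_flatten(f2$ema_params))
})

test_that("cosine schedule starts at the initial rate and decays to near zero", {
  expect_equal(attnseq:::cosine_lr(1e-3, 0, 60), 1e-3)
  expect_lte(attnseq:::cosine_lr(1e-3, 59, 60), 0.01 * 1e-3)
  # monotone decay across epochs
  lrs <- vapply(0:59, attnseq:::cosine_lr, numeric(1), lr0 = 1e-3, epochs = 60)
  expect_true(all(diff(lrs) < 0))
  # the recorded history uses the same schedule
  d <- generate_dataset(tiny_spec(seed = 31))
  fit <- attnseq_fit(d, tiny_config(epochs = 3))
  expect_equal(fit$history$lr,
               vapply(0:2, attnseq:::cosine_lr, numeric(1),
                      lr0 = tiny_config()$learning_rate, epochs = 3))
})

test_that("EMA with decay 0 tracks the raw weights exactly", {
  d <- generate_dataset(tiny_spec(seed = 37))
  fit <- attnseq_fit(d, tiny_config(epochs = 3, ema_decay = 0))
  expect_equal(attnseq:::param_flatten(fit$ema_params),
               attnseq:::param_flatten(fit$params), tolerance = 1e-15)
})

test_that("prediction is deterministic with documented tie-breaking", {
  d <- generate_dataset(tiny_spec(seed = 41))
  fit <- attnseq_fit(d, tiny_config(epochs = 2))
  s <- d$samples[[1]]
  t1 <- predict(fit, s, type = "trace")
  t2 <- predict(fit, s, type = "trace")
  expect_identical(t1, t2)
  probs <- predict(fit, d, type = "prob")
  expect_equal(rowSums(probs), rep(1, length(d$samples)))
  expect_equal(predict(fit, d), max.col(probs, ties.method = "first") - 1L)
})

test_that("training aborts cleanly when the loss diverges", {
  d <- generate_dataset(tiny_spec(seed = 43))
  cfg <- tiny_config(epochs = 30, learning_rate = 1e308, clip_norm = Inf,
                     weight_decay = 10, decay_scope = "all")
  expect_error(attnseq_fit(d, cfg), "diverged|non-finite|finite")
})

test_that("checkpoints round-trip the model through JSON", {
  d <- generate_dataset(tiny_spec(seed = 47))
  cfg <- tiny_config(epochs = 2, relevance = list(R = 0.3 * diag(3)))
  fit <- attnseq_fit(d, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(fit, path)
  fit2 <- load_checkpoint(path)
  expect_equal(attnseq:::param_flatten(fit2$params),
               attnseq:::param_flatten(fit$params), tolerance = 1e-12)
  expect_equal(unclass(fit2$config), unclass(fit$config), tolerance = 1e-12)
  expect_equal(predict(fit2, d), predict(fit, d))
})

test_that("stronger smoothness regularization flattens learned attention", {
  spec <- tiny_spec(n_per_class = 8, seed = 53)
  d <- generate_dataset(spec)
  tv_of <- function(lambda, seed) {
    fit <- attnseq_fit(d, tiny_config(epochs = 15, lambda_reg = lambda,
                                      seed = seed))
    mean(vapply(predict(fit, d, type = "trace"), function(x)
      sum(abs(diff(x$trace$alpha))), numeric(1)))
  }
  tvs <- vapply(c(1, 2), function(s) c(tv_of(0, s), tv_of(1000, s)),
                numeric(2))
  expect_lte(mean(tvs[2, ]), mean(tvs[1, ]))
})
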