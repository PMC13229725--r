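# Brute-force recount used as the independent oracle for the metrics.
brute_metrics <- function(truth, pred, C) {
  cm <- matrix(0L, C, C)
  for (i in seq_along(truth))
    cm[truth[i] + 1, pred[i] + 1] <- cm[truth[i] + 1, pred[i] + 1] + 1L
  prec <- rec <- f1 <- numeric(C)
  for (c in 1:C) {
    tp <- cm[c, c]
    prec[c] <- if (sum(cm[, c]) == 0) 0 else tp / sum(cm[, c])
    rec[c] <- if (sum(cm[c, ]) == 0) 0 else tp / sum(cm[c, ])
    f1[c] <- if (prec[c] + rec[c] == 0) 0
             else 2 * prec[c] * rec[c] / (prec[c] + rec[c])
  }
  list(cm = cm, acc = sum(diag(cm)) / length(truth),
       prec = mean(prec), rec = mean(rec), f1 = mean(f1))
}

test_that("metrics match hand arithmetic on the 2-class confusion matrix", {
  # confusion [[8,2],[3,7]]: 8+7 correct of 20
  truth <- c(rep(0, 10), rep(1, 10))
  pred <- c(rep(0, 8), rep(1, 2), rep(0, 3), rep(1, 7))
  m <- classification_metrics(truth, pred, 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$per_class$precision, c(8 / 11, 7 / 9), tolerance = 1e-12)
  expect_equal(m$per_class$recall, c(0.8, 0.7), tolerance = 1e-12)
  f1 <- c(2 * (8 / 11) * 0.8 / (8 / 11 + 0.8), 2 * (7 / 9) * 0.7 / (7 / 9 + 0.7))
  expect_equal(m$macro_f1, mean(f1), tolerance = 1e-12)
  # all-correct is a fixed point
  m1 <- classification_metrics(0:3, 0:3, 4)
  expect_equal(c(m1$accuracy, m1$macro_precision, m1$macro_recall, m1$macro_f1),
               rep(1, 4))
})

test_that("a class absent from truth and prediction contributes 0 and is flagged", {
  m <- classification_metrics(c(0, 0, 1), c(0, 1, 1), 3)
  expect_equal(m$absent_classes, 2L)
  expect_equal(m$per_class$f1[3], 0)
  expect_equal(m$macro_f1, mean(m$per_class$f1))
})

test_that("metrics agree with a brute-force recount on random label pairs", {
  for (k in 1:100) {
    set_global_seed(900 + k)
    C <- sample(2:6, 1); n <- sample(5:60, 1)
    truth <- sample(0:(C - 1), n, replace = TRUE)
    pred <- sample(0:(C - 1), n, replace = TRUE)
    m <- classification_metrics(truth, pred, C)
    b <- brute_metrics(truth, pred, C)
    expect_equal(unname(unclass(m$confusion)), b$cm)
    expect_equal(m$accuracy, b$acc)
    expect_equal(m$macro_precision, b$prec, tolerance = 1e-12)
    expect_equal(m$macro_recall, b$rec, tolerance = 1e-12)
    expect_equal(m$macro_f1, b$f1, tolerance = 1e-12)
    expect_equal(rowSums(m$confusion),
                 vapply(0:(C - 1), function(c) sum(truth == c), numeric(1)),
                 ignore_attr = TRUE)
  }
})

test_that("attention enrichment matches hand arithmetic and its bounds", {
  # uniform weights are uninformative: enrichment exactly 1
  expect_equal(attention_localization(rep(0.1, 10), c(0, 0.2), rate_hz = 10), 1)
  # all mass inside a 20% window: enrichment hits the 1/f upper bound
  a <- c(0.5, 0.5, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_equal(attention_localization(a, c(0, 0.2), rate_hz = 10), 5)
  # hand case: alpha = (0.7,0.1,0.1,0.1), window = first step only
  expect_equal(attention_localization(c(0.7, 0.1, 0.1, 0.1), c(0, 0.25),
                                      rate_hz = 4), 0.7 / 0.25,
               tolerance = 1e-12)
  # random weights stay within [0, T/|window|] and uniform gives exactly 1
  for (k in 1:20) {
    set_global_seed(950 + k)
    T0 <- sample(5:40, 1)
    alpha <- softmax_normalize(rnorm(T0))
    win <- sort(runif(2, 0, T0 / 10))
    e <- attention_localization(alpha, win, rate_hz = 10)
    if (!is.na(e)) {
      inside <- sum((seq_len(T0) - 1) / 10 >= win[1] &
                    (seq_len(T0) - 1) / 10 < win[2])
      expect_gte(e, 0)
      expect_lte(e, T0 / inside + 1e-12)
    }
  }
})

test_that("evaluation reports are pure, complete and serializable", {
  d <- generate_dataset(tiny_spec(n_per_class = 4, seed = 61))
  fit <- attnseq_fit(d, tiny_config(epochs = 3))
  r1 <- evaluate_model(fit, d)
  r2 <- evaluate_model(fit, d)
  expect_identical(r1, r2)
  expect_equal(sum(r1$confusion), length(d$samples))
  expect_equal(r1$accuracy, sum(diag(r1$confusion)) / sum(r1$confusion))
  expect_equal(r1$n_annotated, length(d$samples))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(r1, path)
  js <- jsonlite::fromJSON(path)
  expect_equal(js$accuracy, r1$accuracy)
  expect_equal(js$seed, fit$seed)
})

test_that("the ablation harness tabulates every variant reproducibly", {
  tr <- generate_dataset(tiny_spec(n_per_class = 4, seed = 67), "train")
  te <- generate_dataset(tiny_spec(n_per_class = 3, seed = 68), "test")
  cfg <- tiny_config(epochs = 3)
  tab <- ablation_suite(tr, te, cfg, seeds = c(1, 2))
  expect_equal(nrow(tab), 4)
  expect_true(all(c("accuracy_mean", "accuracy_sd", "f1_ci95") %in% names(tab)))
  runs <- attr(tab, "runs")
  expect_equal(nrow(runs), 8)                      # 4 variants x 2 seeds
  # the tabulated mean recomputes from the per-run rows
  full_rows <- runs$accuracy[runs$variant == "full model"]
  expect_equal(tab$accuracy_mean[tab$variant == "full model"],
               mean(full_rows), tolerance = 1e-12)
  # rerun is deterministic
  tab2 <- ablation_suite(tr, te, cfg, seeds = c(1, 2))
  expect_identical(tab, tab2)
  expect_error(ablation_suite(tr, te, cfg, seeds = 1), "2")
})
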