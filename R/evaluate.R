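# Metrics, attention-localization scoring, evaluation reports and the
# component-ablation harness.

#' Classification metrics with macro averaging
#'
#' Confusion matrix (rows = truth, columns = prediction), accuracy, and
#' per-class precision/recall/F1 with the 0/0 case defined as 0; macro
#' averages weight all classes equally.  Classes absent from both truth and
#' prediction contribute 0 and are flagged.
#'
#' @param truth,pred Integer vectors of 0-based labels, equal length >= 1.
#' @param class_count Number of classes `C`.
#' @return List with `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `per_class` (data frame), `confusion` (`C x C` integer
#'   matrix) and `absent_classes`.
#' @export
classification_metrics <- function(truth, pred, class_count) {
  stopifnot(length(truth) == length(pred), length(truth) >= 1)
  lev <- 0:(class_count - 1)
  if (any(!truth %in% lev) || any(!pred %in% lev))
    stop("labels outside [0, class_count)", call. = FALSE)
  cm <- table(factor(truth, levels = lev), factor(pred, levels = lev))
  cm <- unclass(cm)
  storage.mode(cm) <- "integer"
  tp <- diag(cm)
  colsum <- colSums(cm); rowsum_ <- rowSums(cm)
  safe_div <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- safe_div(tp, colsum)
  recall <- safe_div(tp, rowsum_)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  absent <- lev[rowsum_ == 0 & colsum == 0]
  list(accuracy = sum(tp) / sum(cm),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1),
       per_class = data.frame(class = lev, support = as.integer(rowsum_),
                              precision = precision, recall = recall,
                              f1 = f1, row.names = NULL),
       confusion = cm,
       absent_classes = as.integer(absent))
}

#' Attention-mass enrichment inside an annotated window
#'
#' The fraction of attention mass falling inside the annotated window,
#' divided by the window's share of the sequence: 1.0 under uniform
#' attention, up to `T / |window|` when all mass is inside.  Operationalizes
#' the check that the model attends to the clinically informative movement
#' phase.
#'
#' @param trace An attention trace (list with `alpha`), or a bare numeric
#'   weight vector.
#' @param window Numeric `c(t_start, t_end)` in seconds (half-open).
#' @param rate_hz Frame rate of the time base `alpha` lives on; defaults to
#'   the rate recorded in the trace.
#' @return Nonnegative enrichment score.
#' @export
attention_localization <- function(trace, window, rate_hz = NULL) {
  alpha <- if (is.list(trace)) trace$alpha else trace
  if (is.null(rate_hz) && is.list(trace)) rate_hz <- trace$time_rate_hz
  stopifnot(!is.null(rate_hz), length(window) == 2, window[1] < window[2])
  T0 <- length(alpha)
  t <- (seq_len(T0) - 1) / rate_hz
  inside <- t >= window[1] & t < window[2]
  if (!any(inside)) return(NA_real_)
  (sum(alpha[inside]) / sum(alpha)) / (sum(inside) / T0)
}

#' Evaluate a fitted model on a dataset
#'
#' Computes classification metrics, the confusion matrix, and — over the
#' samples carrying motif annotations — the mean attention-mass enrichment.
#' The report is a pure function of the model's predictions and the data.
#'
#' @param model A fitted `attnseq` object.
#' @param dataset A [sequence_dataset()].
#' @param use_ema Evaluate with the EMA weights (default) or raw weights.
#' @return An object of class `attnseq_report`.
#' @export
evaluate_model <- function(model, dataset, use_ema = TRUE) {
  samples <- as_sample_list(dataset)
  traces <- predict(model, samples, type = "trace", use_ema = use_ema)
  truth <- vapply(samples, function(s) s$label, integer(1))
  pred <- vapply(traces, function(x) x$label, integer(1))
  met <- classification_metrics(truth, pred, model$config$class_count)
  enr <- vapply(seq_along(samples), function(i) {
    ann <- samples[[i]]$annotation
    if (is.null(ann)) return(NA_real_)
    attention_localization(traces[[i]]$trace, ann)
  }, numeric(1))
  rep <- list(accuracy = met$accuracy,
              macro_precision = met$macro_precision,
              macro_recall = met$macro_recall,
              macro_f1 = met$macro_f1,
              per_class = met$per_class,
              confusion = met$confusion,
              absent_classes = met$absent_classes,
              n_samples = length(samples),
              localization_enrichment = if (all(is.na(enr))) NA_real_
                                        else mean(enr, na.rm = TRUE),
              n_annotated = sum(!is.na(enr)),
              seed = model$seed,
              config_digest = config_digest(unclass(model$config)))
  class(rep) <- "attnseq_report"
  rep
}

#' @export
print.attnseq_report <- function(x, ...) {
  cat("<attnseq_report>  n =", x$n_samples, "\n")
  cat(sprintf("  accuracy %.4f | macro P %.4f R %.4f F1 %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  if (!is.na(x$localization_enrichment))
    cat(sprintf("  attention enrichment %.3f over %d annotated samples\n",
                x$localization_enrichment, x$n_annotated))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report An `attnseq_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  obj <- unclass(report)
  obj$confusion <- apply(report$confusion, 1, as.integer, simplify = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", dataframe = "columns")
  invisible(path)
}

#' Component-ablation suite
#'
#' Trains and evaluates four model variants per seed — the full model,
#' video-only (fusion ablated), mean pooling in place of attention
#' (hierarchy ablated), and `lambda_reg = 0` (temporal regularization
#' ablated) — and tabulates mean, standard deviation and t-based 95%
#' confidence half-width of each metric across seeds.
#'
#' @param train_data,test_data Training and evaluation datasets.
#' @param config Base [attnseq_config()]; each run overrides its `seed`.
#' @param seeds Integer vector of at least 2 seeds.
#' @param variants Subset of `c("full", "no_fusion", "no_attention",
#'   "no_reg")` to run.
#' @param verbose Print progress.
#' @return Data frame with one row per variant and mean/sd/ci95 columns per
#'   metric; the per-run metrics are attached as attribute `"runs"`.
#' @export
ablation_suite <- function(train_data, test_data, config, seeds,
                           variants = c("full", "no_fusion", "no_attention",
                                        "no_reg"),
                           verbose = FALSE) {
  stopifnot(length(seeds) >= 2)
  variants <- match.arg(variants, several.ok = TRUE)
  labels <- c(full = "full model",
              no_fusion = "w/o multimodal fusion (video only)",
              no_attention = "w/o hierarchical attention (mean pooling)",
              no_reg = "w/o temporal regularization")
  runs <- list()
  for (vt in variants) {
    for (sd_ in seeds) {
      cfg <- config
      cfg$seed <- as.integer(sd_)
      if (vt == "no_fusion") cfg$modalities <- "video"
      if (vt == "no_attention") cfg$pooling <- "mean"
      if (vt == "no_reg") cfg$lambda_reg <- 0
      if (verbose) message("ablation: ", vt, " seed ", sd_)
      fit <- attnseq_fit(train_data, cfg)
      rep <- evaluate_model(fit, test_data)
      runs[[length(runs) + 1L]] <- data.frame(
        variant = labels[[vt]], seed = sd_,
        accuracy = rep$accuracy, precision = rep$macro_precision,
        recall = rep$macro_recall, f1 = rep$macro_f1,
        enrichment = rep$localization_enrichment)
    }
  }
  runs <- do.call(rbind, runs)
  order_ <- unique(runs$variant)
  agg <- function(metric) {
    m <- tapply(runs[[metric]], runs$variant, mean)
    s <- tapply(runs[[metric]], runs$variant, stats::sd)
    n <- tapply(runs[[metric]], runs$variant, length)
    ci <- stats::qt(0.975, pmax(n - 1, 1)) * s / sqrt(n)
    df <- data.frame(mean = as.numeric(m), sd = as.numeric(s),
                     ci95 = as.numeric(ci), row.names = names(m))
    df[order_, ]
  }
  out <- data.frame(variant = order_)
  for (metric in c("accuracy", "precision", "recall", "f1")) {
    a <- agg(metric)
    names(a) <- paste0(metric, c("_mean", "_sd", "_ci95"))
    out <- cbind(out, a)
  }
  rownames(out) <- NULL
  attr(out, "runs") <- runs
  out
}
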