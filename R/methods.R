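# S3 methods for the fitted model.

#' @export
print.attnseq <- function(x, ...) {
  cfg <- x$config
  cat("<attnseq> hierarchical-attention sequence classifier\n")
  cat(sprintf("  classes: %d | pooling: %s | modalities: %s\n",
              cfg$class_count, cfg$pooling, cfg$modalities))
  cat(sprintf("  fused dim: %d | attention dim: %d | segments: %d\n",
              fused_dim(cfg), cfg$attn_dim, cfg$n_segments))
  h <- x$history
  if (!is.null(h) && nrow(h))
    cat(sprintf("  trained %d epochs (seed %d); final loss %.4f, train acc %.3f\n",
                nrow(h), x$seed, h$total_loss[nrow(h)],
                h$train_accuracy[nrow(h)]))
  invisible(x)
}

#' @export
summary.attnseq <- function(object, ...) {
  h <- object$history
  np <- length(param_flatten(object$params))
  cat("Hierarchical-attention sequence classifier\n\n")
  print(object)
  cat(sprintf("  learnable parameters: %d\n", np))
  cat(sprintf("  lambda (temporal smoothness): %g | weight decay: %g (%s)\n",
              object$config$lambda_reg, object$config$weight_decay,
              object$config$decay_scope))
  if (!is.null(h) && nrow(h) > 1) {
    cat("\nTraining history (first/last epochs):\n")
    print(h[unique(c(1, nrow(h))), c("epoch", "lr", "total_loss",
                                     "cross_entropy", "temporal_reg",
                                     "train_accuracy")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Extract model parameters
#'
#' @param object A fitted `attnseq` model.
#' @param ema Return the EMA weights instead of the raw final weights.
#' @param ... Unused.
#' @return The nested parameter list (`video`, `sensor`, `attn`, `head`).
#' @export
coef.attnseq <- function(object, ema = FALSE, ...) {
  if (ema) object$ema_params else object$params
}

#' Plot the attention profile of one sample
#'
#' Draws the time-step attention weights over time, shades the annotated
#' motif window if present, marks the uniform level 1/T, and (for
#' hierarchical pooling) overlays the segment weights.
#'
#' @param x A fitted `attnseq` model.
#' @param sample A [sequence_sample()] to explain.
#' @param use_ema Use the EMA weights.
#' @param ... Passed to [graphics::plot()].
#' @return The attention trace, invisibly.
#' @export
plot.attnseq <- function(x, sample, use_ema = TRUE, ...) {
  tr <- predict(x, sample, type = "trace", use_ema = use_ema)[[1]]
  alpha <- tr$trace$alpha
  rate <- tr$trace$time_rate_hz
  t <- (seq_along(alpha) - 1) / rate
  graphics::plot(t, alpha, type = "h", lwd = 2, col = "grey30",
                 xlab = "time [s]", ylab = expression(alpha[t]),
                 main = sprintf("%s: predicted class %d",
                                sample$sample_id, tr$label), ...)
  graphics::abline(h = 1 / length(alpha), lty = 3, col = "grey60")
  if (!is.null(sample$annotation))
    graphics::rect(sample$annotation[1], 0, sample$annotation[2],
                   max(alpha), col = grDevices::adjustcolor("tomato", 0.2),
                   border = NA)
  if (!is.null(tr$trace$beta)) {
    K <- length(tr$trace$beta)
    part <- segment_partition(length(alpha), K)
    mids <- (part[, "start"] + part[, "end"]) / 2 / rate
    graphics::points(mids, tr$trace$beta * max(alpha) / max(tr$trace$beta),
                     pch = 18, col = "steelblue")
  }
  invisible(tr$trace)
}
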