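# Model assembly, losses, analytic gradients and the training loop.
#
# The full forward path for one sample is:
#   encoders -> late fusion -> attention pooling -> 2-layer classifier head
# and the per-sample objective is
#   L = CE(softmax(logits), label) + lambda * sum_t (alpha_t - alpha_{t-1})^2
# with an L2 penalty on the attention parameters (optionally all parameters)
# added at the batch level.  Gradients are derived by hand, layer by layer;
# they are validated against central finite differences in the test suite.

#' Cross-entropy of a predicted class distribution
#'
#' `-log y_pred[label]` with the probability clipped to `[1e-12, 1]` so the
#' loss stays finite for degenerate predictions.
#'
#' @param y_pred Probability vector over classes (sums to 1 within 1e-6).
#' @param label 0-based true class index.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(y_pred, label) {
  if (abs(sum(y_pred) - 1) > 1e-6)
    stop("y_pred does not sum to 1", call. = FALSE)
  label <- as.integer(label)
  if (label < 0 || label >= length(y_pred))
    stop("label ", label, " outside [0, ", length(y_pred), ")", call. = FALSE)
  -log(min(max(y_pred[label + 1L], 1e-12), 1))
}

#' First-order temporal smoothness penalty on attention weights
#'
#' `sum_{t=2}^T (alpha_t - alpha_{t-1})^2`; zero for constant weights and
#' for sequences of length 1.
#'
#' @param alpha Numeric vector of attention weights.
#' @return Nonnegative scalar.
#' @export
temporal_reg <- function(alpha) {
  if (length(alpha) <= 1) return(0)
  sum(diff(alpha)^2)
}

# d temporal_reg / d alpha
temporal_reg_grad <- function(alpha) {
  T0 <- length(alpha)
  g <- numeric(T0)
  if (T0 <= 1) return(g)
  d <- diff(alpha)
  g[-1] <- g[-1] + 2 * d
  g[-T0] <- g[-T0] - 2 * d
  g
}

# Resample a sample's sensor stream to the configured common rate.
preprocess_sample <- function(s, config) {
  if (s$sensor_rate_hz != config$sensor_resample_hz) {
    s$sensor_stream <- resample_stream(s$sensor_stream, s$sensor_rate_hz,
                                       config$sensor_resample_hz)
    s$sensor_rate_hz <- config$sensor_resample_hz
  }
  s
}

as_sample_list <- function(data) {
  if (inherits(data, "sequence_dataset")) data$samples
  else if (inherits(data, "sequence_sample")) list(data)
  else data
}

# ---------------------------------------------------------------------------
# Forward pass (one sample).  Returns class probabilities, the attention
# trace, and every intermediate needed by the backward pass.
forward_sample <- function(s, params, config, train = FALSE) {
  s <- preprocess_sample(s, config)
  cache <- list(sample = s)
  Ev <- NULL
  if (config$modalities != "sensor") {
    X <- s$video_stream
    vc <- vector("list", length(params$video$layers))
    for (l in seq_along(params$video$layers)) {
      vc[[l]] <- rnn_bidir_forward(X, params$video$layers[[l]]$fwd,
                                   params$video$layers[[l]]$bwd)
      X <- vc[[l]]$H
    }
    cache$video <- vc
    Ev <- X
  }
  Es <- NULL
  if (config$modalities != "video") {
    cache$sensor <- sensor_forward_cache(s$sensor_stream, params)
    Es <- cache$sensor$H
  }
  if (config$modalities == "both") {
    tv <- (seq_len(nrow(Ev)) - 1) / s$video_rate_hz
    iw <- interp_weights(nrow(Es), s$sensor_rate_hz, tv)
    cache$iw <- iw
    H <- cbind(Ev, interp_apply(Es, iw))
    x_raw <- s$video_stream
    cache$time_rate <- s$video_rate_hz
  } else if (config$modalities == "video") {
    H <- Ev
    x_raw <- s$video_stream
    cache$time_rate <- s$video_rate_hz
  } else {
    H <- Es
    x_raw <- s$sensor_stream
    cache$time_rate <- s$sensor_rate_hz
  }
  cache$H <- H
  cache$x_raw <- x_raw
  rel <- if (!is.null(config$relevance)) config$relevance$R
  T0 <- nrow(H)

  at <- list()
  if (config$pooling == "mean") {
    at$alpha <- rep(1 / T0, T0)
    r <- colMeans(H)
    at$reg <- 0
  } else if (config$pooling == "multiscale") {
    XR <- if (!is.null(rel)) x_raw %*% t(rel)
    wins <- list()
    for (w in config$windows) {
      ws <- window_starts(T0, w[1], w[2])
      for (st in ws$starts) {
        idx <- (st + 1):(st + ws$size)
        pre <- sweep(H[idx, , drop = FALSE] %*% t(params$attn$W_h), 2,
                     params$attn$b_h, "+")
        if (!is.null(rel))
          pre <- pre + XR[idx, , drop = FALSE] %*% t(params$attn$P)
        U <- tanh(pre)
        a <- softmax_normalize(as.vector(U %*% params$attn$v))
        wins[[length(wins) + 1L]] <-
          list(idx = idx, U = U, alpha = a,
               z = as.vector(crossprod(H[idx, , drop = FALSE], a)))
      }
    }
    nw <- length(wins)
    Z <- do.call(rbind, lapply(wins, `[[`, "z"))
    r <- if (config$window_agg == "mean") colMeans(Z) else colSums(Z)
    at$wins <- wins
    at$reg <- mean(vapply(wins, function(w) temporal_reg(w$alpha), numeric(1)))
    prof <- numeric(T0)
    for (w in wins) prof[w$idx] <- prof[w$idx] + w$alpha
    at$alpha <- prof / sum(prof)
    at$window_alphas <- lapply(wins, `[[`, "alpha")
  } else {
    XR <- if (!is.null(rel)) x_raw %*% t(rel)
    pre <- sweep(H %*% t(params$attn$W_h), 2, params$attn$b_h, "+")
    if (!is.null(rel)) pre <- pre + XR %*% t(params$attn$P)
    U <- tanh(pre)
    e <- as.vector(U %*% params$attn$v)
    alpha <- softmax_normalize(e)
    at$U <- U; at$XR <- XR; at$alpha <- alpha
    at$z <- as.vector(crossprod(H, alpha))
    at$reg <- temporal_reg(alpha)
    if (config$pooling == "timestep") {
      r <- at$z
    } else {
      K <- min(config$n_segments, T0)
      part <- segment_partition(T0, K)
      seg_of <- rep(seq_len(K), times = part[, "end"] - part[, "start"])
      S <- segment_vectors(alpha, H, part,
                           renormalize = config$renormalize_segments)
      Us <- tanh(sweep(S %*% t(params$attn$W_s), 2, params$attn$b_s, "+"))
      f <- as.vector(Us %*% params$attn$u)
      beta <- softmax_normalize(f)
      r <- as.vector(crossprod(S, beta))
      at$part <- part; at$seg_of <- seg_of; at$S <- S
      at$Us <- Us; at$beta <- beta
    }
  }
  cache$at <- at
  cache$r <- r

  p <- config$dropout
  if (train && p > 0) {
    mask_r <- (runif(length(r)) >= p) / (1 - p)
    cache$mask_r <- mask_r
    rd <- r * mask_r
  } else rd <- r
  g1 <- tanh(as.vector(params$head$W1 %*% rd) + params$head$b1)
  if (train && p > 0) {
    mask1 <- (runif(length(g1)) >= p) / (1 - p)
    cache$mask1 <- mask1
    g1d <- g1 * mask1
  } else g1d <- g1
  logits <- as.vector(params$head$W2 %*% g1d) + params$head$b2
  if (!all(is.finite(logits)))
    stop("training diverged: non-finite activations in the classifier head",
         call. = FALSE)
  probs <- softmax_normalize(logits)
  cache$rd <- rd; cache$g1 <- g1; cache$g1d <- g1d; cache$probs <- probs

  trace <- list(alpha = at$alpha,
                window_alphas = at$window_alphas,
                beta = at$beta,
                segment_vectors = at$S,
                z = at$z, r = r,
                time_rate_hz = cache$time_rate)
  list(probs = probs, trace = trace, reg = at$reg, cache = cache)
}

# ---------------------------------------------------------------------------
# Backward pass for one sample; returns the gradient tree of
# CE + lambda * reg w.r.t. all parameters.
backward_sample <- function(fw, params, config, label, lambda) {
  cache <- fw$cache
  H <- cache$H
  T0 <- nrow(H)
  d_f <- ncol(H)
  g <- param_zeros_like(params)

  dlogits <- cache$probs
  dlogits[label + 1L] <- dlogits[label + 1L] - 1
  g$head$W2 <- outer(dlogits, cache$g1d)
  g$head$b2 <- dlogits
  dg1d <- as.vector(crossprod(params$head$W2, dlogits))
  dg1 <- if (!is.null(cache$mask1)) dg1d * cache$mask1 else dg1d
  da1 <- dg1 * (1 - cache$g1^2)
  g$head$W1 <- outer(da1, cache$rd)
  g$head$b1 <- da1
  drd <- as.vector(crossprod(params$head$W1, da1))
  dr <- if (!is.null(cache$mask_r)) drd * cache$mask_r else drd

  at <- cache$at
  dH <- matrix(0, T0, d_f)
  rel <- if (!is.null(config$relevance)) config$relevance$R

  score_backward <- function(de, U, Hsub, XRsub) {
    # e = U v, U = tanh(W_h h + b_h [+ P R x]); accumulates into g$attn, and
    # returns the gradient w.r.t. the rows of Hsub.
    g$attn$v <<- g$attn$v + as.vector(crossprod(U, de))
    dpre <- (de %o% params$attn$v) * (1 - U^2)
    g$attn$W_h <<- g$attn$W_h + crossprod(dpre, Hsub)
    g$attn$b_h <<- g$attn$b_h + colSums(dpre)
    if (!is.null(rel))
      g$attn$P <<- g$attn$P + crossprod(dpre, XRsub)
    dpre %*% params$attn$W_h
  }

  if (config$pooling == "mean") {
    dH <- dH + matrix(dr / T0, T0, d_f, byrow = TRUE)
  } else if (config$pooling == "multiscale") {
    nw <- length(at$wins)
    for (w in at$wins) {
      idx <- w$idx
      dz <- if (config$window_agg == "mean") dr / nw else dr
      Hsub <- H[idx, , drop = FALSE]
      dalpha <- as.vector(Hsub %*% dz) +
        lambda * temporal_reg_grad(w$alpha) / nw
      dH[idx, ] <- dH[idx, ] + w$alpha %o% dz
      de <- w$alpha * (dalpha - sum(dalpha * w$alpha))
      XRsub <- if (!is.null(rel)) (cache$x_raw %*% t(rel))[idx, , drop = FALSE]
      dH[idx, ] <- dH[idx, ] + score_backward(de, w$U, Hsub, XRsub)
    }
  } else {
    alpha <- at$alpha
    if (config$pooling == "timestep") {
      dalpha <- as.vector(H %*% dr)
      dH <- dH + alpha %o% dr
    } else {
      S <- at$S; beta <- at$beta; Us <- at$Us
      dbeta <- as.vector(S %*% dr)
      dS <- beta %o% dr
      df <- beta * (dbeta - sum(dbeta * beta))
      dpre_s <- (df %o% params$attn$u) * (1 - Us^2)
      g$attn$W_s <- g$attn$W_s + crossprod(dpre_s, S)
      g$attn$b_s <- g$attn$b_s + colSums(dpre_s)
      g$attn$u <- g$attn$u + as.vector(crossprod(Us, df))
      dS <- dS + dpre_s %*% params$attn$W_s
      seg <- at$seg_of
      if (config$renormalize_segments) {
        part <- at$part
        dalpha <- numeric(T0)
        for (k in seq_len(nrow(part))) {
          idx <- (part[k, "start"] + 1):part[k, "end"]
          A <- sum(alpha[idx])
          proj <- as.vector(H[idx, , drop = FALSE] %*% dS[k, ])
          dalpha[idx] <- (proj - sum(dS[k, ] * S[k, ])) / A
          dH[idx, ] <- dH[idx, ] + (alpha[idx] / A) %o% dS[k, ]
        }
      } else {
        dalpha <- rowSums(H * dS[seg, , drop = FALSE])
        dH <- dH + alpha * dS[seg, , drop = FALSE]
      }
    }
    dalpha <- dalpha + lambda * temporal_reg_grad(alpha)
    de <- alpha * (dalpha - sum(dalpha * alpha))
    dH <- dH + score_backward(de, at$U, H, at$XR)
  }

  # split the fused gradient back into the modality branches
  if (config$modalities == "both") {
    dv2 <- 2L * config$video_hidden
    dEv <- dH[, seq_len(dv2), drop = FALSE]
    dEs2 <- dH[, dv2 + seq_len(d_f - dv2), drop = FALSE]
    Es <- cache$sensor$H
    dEs <- matrix(0, nrow(Es), ncol(Es))
    if (nrow(Es) == 1) {
      dEs[1, ] <- colSums(dEs2)
    } else {
      iw <- cache$iw
      a1 <- rowsum((1 - iw$w) * dEs2, group = iw$j0)
      dEs[as.integer(rownames(a1)), ] <-
        dEs[as.integer(rownames(a1)), , drop = FALSE] + a1
      a2 <- rowsum(iw$w * dEs2, group = iw$j0 + 1L)
      dEs[as.integer(rownames(a2)), ] <-
        dEs[as.integer(rownames(a2)), , drop = FALSE] + a2
    }
  } else if (config$modalities == "video") {
    dEv <- dH; dEs <- NULL
  } else {
    dEv <- NULL; dEs <- dH
  }

  if (!is.null(dEv)) {
    dX <- dEv
    for (l in rev(seq_along(params$video$layers))) {
      bb <- rnn_bidir_backward(cache$video[[l]],
                               params$video$layers[[l]]$fwd,
                               params$video$layers[[l]]$bwd, dX)
      g$video$layers[[l]]$fwd <- bb$fwd
      g$video$layers[[l]]$bwd <- bb$bwd
      dX <- bb$dX
    }
  }
  if (!is.null(dEs)) {
    sc <- cache$sensor
    bb <- rnn_bidir_backward(sc$rnn, params$sensor$rnn$fwd,
                             params$sensor$rnn$bwd, dEs)
    g$sensor$rnn$fwd <- bb$fwd
    g$sensor$rnn$bwd <- bb$bwd
    dact <- bb$dX
    for (i in rev(seq_along(params$sensor$conv))) {
      cc <- sc$conv[[i]]
      dpre <- dact * (1 - cc$act^2)
      cb <- conv1d_backward(cc$X, params$sensor$conv[[i]]$W, dpre)
      g$sensor$conv[[i]]$W <- cb$dW
      g$sensor$conv[[i]]$b <- cb$db
      dact <- cb$dX
    }
  }
  g
}

# Mean loss and gradient over a batch of samples.
loss_grad_batch <- function(samples, params, config, train = FALSE,
                            lambda = config$lambda_reg,
                            weight_decay = config$weight_decay,
                            want_grad = TRUE) {
  n <- length(samples)
  stopifnot(n >= 1)
  ce_sum <- 0; reg_sum <- 0
  gsum <- NULL
  preds <- integer(n); labels <- integer(n)
  for (i in seq_len(n)) {
    s <- samples[[i]]
    fw <- forward_sample(s, params, config, train = train)
    ce_sum <- ce_sum + cross_entropy(fw$probs, s$label)
    reg_sum <- reg_sum + fw$reg
    preds[i] <- which.max(fw$probs) - 1L
    labels[i] <- s$label
    if (want_grad) {
      gi <- backward_sample(fw, params, config, s$label, lambda)
      gsum <- if (is.null(gsum)) gi else param_map2(gsum, gi, `+`)
    }
  }
  ce <- ce_sum / n; reg <- reg_sum / n
  pen <- 0
  if (weight_decay > 0) {
    pen <- weight_decay * (if (config$decay_scope == "attention")
      param_sumsq(params$attn) else param_sumsq(params))
  }
  out <- list(total = ce + lambda * reg + pen,
              cross_entropy = ce, temporal_reg = reg,
              weight_penalty = pen, lambda = lambda,
              preds = preds, labels = labels)
  if (want_grad) {
    grads <- param_map(gsum, function(x) x / n)
    if (weight_decay > 0) {
      if (config$decay_scope == "attention")
        grads$attn <- param_map2(grads$attn, params$attn,
                                 function(gl, pl) gl + 2 * weight_decay * pl)
      else
        grads <- param_map2(grads, params,
                            function(gl, pl) gl + 2 * weight_decay * pl)
    }
    out$gradient <- grads
  }
  out
}

#' Combined training objective
#'
#' Mean cross-entropy over the batch, plus `lambda_reg` times the mean
#' temporal smoothness penalty of the attention weights, plus the L2 weight
#' penalty on the configured parameter scope.  Components are returned
#' separately; `gradient = TRUE` additionally returns the analytic gradient
#' tree (validated against finite differences in the test suite).  Dropout
#' is never applied here, so the value is deterministic.
#'
#' @param batch A [sequence_dataset()], a list of samples, or one sample.
#' @param params Parameter tree from [attnseq_init_params()].
#' @param config An [attnseq_config()].
#' @param lambda_reg,weight_decay Override the configured coefficients.
#' @param gradient Also compute the analytic gradient.
#' @return List with `total`, `cross_entropy`, `temporal_reg`,
#'   `weight_penalty` (and `gradient` if requested).
#' @export
total_loss <- function(batch, params, config,
                       lambda_reg = config$lambda_reg,
                       weight_decay = config$weight_decay,
                       gradient = FALSE) {
  samples <- as_sample_list(batch)
  if (length(samples) == 0) stop("empty batch", call. = FALSE)
  out <- loss_grad_batch(samples, params, config, train = FALSE,
                         lambda = lambda_reg, weight_decay = weight_decay,
                         want_grad = gradient)
  out$preds <- NULL; out$labels <- NULL
  out
}

# Cosine-annealed learning rate for epoch e (0-based) of E.
cosine_lr <- function(lr0, epoch, epochs) {
  lr0 * 0.5 * (1 + cos(pi * epoch / epochs))
}

#' Fit the attention classifier
#'
#' Trains the full model (modality encoders, hierarchical attention, and
#' classifier head) with Adam under a cosine-annealed learning rate,
#' global gradient-norm clipping, and an exponential moving average (EMA) of
#' the parameters; the bias-corrected EMA weights are used for prediction by
#' default.  Training is deterministic given `config$seed`.
#'
#' @param data Training data: a [sequence_dataset()] or list of samples.
#' @param config An [attnseq_config()]; `config$class_count` must match the
#'   data.
#' @param val_data Optional validation dataset scored once per epoch.
#' @param verbose Print per-epoch progress.
#' @return An object of class `attnseq` with components `params`,
#'   `ema_params`, `config`, `history` (one row per epoch) and `seed`.
#' @export
attnseq_fit <- function(data, config, val_data = NULL, verbose = FALSE) {
  samples <- as_sample_list(data)
  if (length(samples) == 0) stop("cannot train on an empty dataset",
                                 call. = FALSE)
  if (inherits(data, "sequence_dataset") &&
      data$class_count != config$class_count)
    stop("config$class_count does not match the dataset", call. = FALSE)
  set_global_seed(config$seed)
  samples <- lapply(samples, preprocess_sample, config = config)
  val_samples <- if (!is.null(val_data))
    lapply(as_sample_list(val_data), preprocess_sample, config = config)
  params <- attnseq_init_params(config)
  skel <- params
  pv <- param_flatten(params)
  mv <- numeric(length(pv)); vv <- numeric(length(pv))
  emav <- numeric(length(pv))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- length(samples)
  E <- config$epochs
  hist <- vector("list", E)
  for (epoch in seq_len(E) - 1L) {
    lr <- cosine_lr(config$learning_rate, epoch, E)
    ord <- sample.int(n)
    nb <- ceiling(n / config$batch_size)
    tot <- ce <- reg <- pen <- 0
    correct <- 0L
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * config$batch_size + 1):min(bi * config$batch_size, n)]
      lg <- loss_grad_batch(samples[idx], params, config, train = TRUE)
      if (!is.finite(lg$total))
        stop("training diverged: non-finite loss at epoch ", epoch,
             call. = FALSE)
      gv <- param_flatten(lg$gradient)
      gn <- sqrt(sum(gv^2))
      if (is.finite(config$clip_norm) && gn > config$clip_norm)
        gv <- gv * (config$clip_norm / gn)
      step <- step + 1L
      mv <- b1 * mv + (1 - b1) * gv
      vv <- b2 * vv + (1 - b2) * gv^2
      mhat <- mv / (1 - b1^step)
      vhat <- vv / (1 - b2^step)
      pv <- pv - lr * mhat / (sqrt(vhat) + eps)
      emav <- config$ema_decay * emav + (1 - config$ema_decay) * pv
      params <- param_unflatten(pv, skel)
      tot <- tot + lg$total * length(idx)
      ce <- ce + lg$cross_entropy * length(idx)
      reg <- reg + lg$temporal_reg * length(idx)
      pen <- pen + lg$weight_penalty * length(idx) / n
      correct <- correct + sum(lg$preds == lg$labels)
    }
    val_acc <- NA_real_
    if (!is.null(val_samples)) {
      vp <- vapply(val_samples, function(s)
        which.max(forward_sample(s, params, config)$probs) - 1L, integer(1))
      vl <- vapply(val_samples, function(s) s$label, integer(1))
      val_acc <- mean(vp == vl)
    }
    hist[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = lr, total_loss = tot / n,
      cross_entropy = ce / n, temporal_reg = reg / n, weight_penalty = pen,
      train_accuracy = correct / n, val_accuracy = val_acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f  acc %.3f",
                      epoch, lr, tot / n, correct / n))
  }
  ema_corr <- if (step > 0) emav / (1 - config$ema_decay^step) else pv
  structure(list(params = params,
                 ema_params = param_unflatten(ema_corr, skel),
                 config = config,
                 history = do.call(rbind, hist),
                 seed = config$seed,
                 steps = step),
            class = "attnseq")
}

#' Predict classes, probabilities or attention traces
#'
#' Inference is deterministic (dropout off) and, by default, uses the
#' bias-corrected EMA weights.  Ties in the class probabilities are broken
#' toward the lowest class index.
#'
#' @param object A fitted `attnseq` model.
#' @param newdata A [sequence_dataset()], list of samples, or one sample.
#' @param type `"class"` (0-based labels), `"prob"` (matrix of class
#'   probabilities) or `"trace"` (list per sample with `label`, `probs` and
#'   the full attention trace).
#' @param use_ema Use the EMA weights (`TRUE`, default) or the raw final
#'   weights.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.attnseq <- function(object, newdata, type = c("class", "prob", "trace"),
                            use_ema = TRUE, ...) {
  type <- match.arg(type)
  samples <- as_sample_list(newdata)
  params <- if (use_ema) object$ema_params else object$params
  fws <- lapply(samples, forward_sample, params = params,
                config = object$config)
  probs <- do.call(rbind, lapply(fws, `[[`, "probs"))
  labels <- max.col(probs, ties.method = "first") - 1L
  switch(type,
         class = labels,
         prob = probs,
         trace = lapply(seq_along(fws), function(i)
           list(sample_id = samples[[i]]$sample_id,
                label = labels[i], probs = probs[i, ],
                trace = fws[[i]]$trace)))
}

# ---------------------------------------------------------------------------
# Checkpoints: a single JSON file holding the config, seed, history and all
# parameter tensors with named keys.

params_to_plain <- function(p) {
  if (is_param_leaf(p))
    return(list(.dim = if (is.null(dim(p))) length(p) else dim(p),
                .data = as.vector(p)))
  lapply(p, params_to_plain)
}

params_from_plain <- function(x) {
  if (is.list(x) && !is.null(x$.dim)) {
    v <- as.numeric(x$.data)
    if (length(x$.dim) > 1) dim(v) <- x$.dim
    return(v)
  }
  lapply(x, params_from_plain)
}

#' Save or load a model checkpoint
#'
#' Checkpoints are single JSON files with a header (configuration, seed,
#' training history) and all parameter tensors, so they are portable and
#' human-inspectable.
#'
#' @param model A fitted `attnseq` object.
#' @param path Checkpoint file path.
#' @return `load_checkpoint()` returns the restored `attnseq` object;
#'   `save_checkpoint()` returns `path` invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "attnseq"))
  cfg <- unclass(model$config)
  if (!is.null(cfg$relevance) && !is.null(cfg$relevance$R))
    cfg$relevance$R <- apply(cfg$relevance$R, 1, as.numeric, simplify = FALSE)
  obj <- list(header = list(package = "attnseq", format = 1L,
                            config = cfg, seed = model$seed,
                            steps = model$steps,
                            history = model$history),
              params = params_to_plain(model$params),
              ema_params = params_to_plain(model$ema_params))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cfg <- obj$header$config
  cfg$relevance <- normalize_relevance(cfg$relevance)
  cfg$windows <- normalize_windows(cfg$windows)
  config <- do.call(attnseq_config, cfg)
  structure(list(params = params_from_plain(obj$params),
                 ema_params = params_from_plain(obj$ema_params),
                 config = config,
                 history = as.data.frame(lapply(obj$header$history, unlist)),
                 seed = obj$header$seed,
                 steps = obj$header$steps),
            class = "attnseq")
}
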