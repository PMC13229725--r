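# Per-modality temporal encoders and late fusion.
#
# Video branch: stacked bidirectional tanh recurrences over the per-frame
# embedding stream (the frame backbone is an input contract: the video
# stream already is one embedding vector per frame).  Sensor branch: a stack
# of same-length 1-D convolutions followed by one bidirectional recurrence.
# Fusion interpolates the sensor embeddings onto the video frame timestamps
# and concatenates row-wise, so the fused sequence has one row per video
# frame and d_f = d_v' + d_s' columns.

kaiming <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

init_rnn_cell <- function(d_in, h) {
  list(Wx = kaiming(d_in, h, d_in),
       Wh = matrix(rnorm(h * h, sd = sqrt(1 / h)), h, h),
       b = numeric(h))
}

init_conv_layer <- function(k, d_in, d_out) {
  W <- array(rnorm(k * d_in * d_out, sd = sqrt(2 / (k * d_in))),
             dim = c(k, d_in, d_out))
  list(W = W, b = numeric(d_out))
}

#' Initialize all learnable parameters
#'
#' He-style Gaussian initialization, scaled by fan-in, for every weight
#' tensor; biases and the relevance projection start at zero (a zero
#' projection makes the domain-relevance adjustment initially inert).
#' Drawn from the global RNG: call [set_global_seed()] first for
#' reproducibility.
#'
#' @param config An [attnseq_config()].
#' @return Nested parameter list with components `video`, `sensor`, `attn`
#'   and `head`.
#' @export
attnseq_init_params <- function(config) {
  cfg <- config
  d_f <- fused_dim(cfg)
  video <- NULL
  if (cfg$modalities != "sensor") {
    layers <- vector("list", cfg$video_layers)
    d_in <- cfg$d_v
    for (l in seq_len(cfg$video_layers)) {
      layers[[l]] <- list(fwd = init_rnn_cell(d_in, cfg$video_hidden),
                          bwd = init_rnn_cell(d_in, cfg$video_hidden))
      d_in <- 2L * cfg$video_hidden
    }
    video <- list(layers = layers)
  }
  sensor <- NULL
  if (cfg$modalities != "video") {
    conv <- list()
    d_in <- cfg$d_s
    for (ch in cfg$sensor_conv_channels) {
      conv[[length(conv) + 1L]] <- init_conv_layer(cfg$sensor_conv_kernel,
                                                   d_in, ch)
      d_in <- ch
    }
    sensor <- list(conv = conv,
                   rnn = list(fwd = init_rnn_cell(d_in, cfg$sensor_hidden),
                              bwd = init_rnn_cell(d_in, cfg$sensor_hidden)))
  }
  a <- cfg$attn_dim
  attn <- list(W_h = kaiming(a, d_f, d_f), b_h = numeric(a),
               v = kaiming(a, 1, a)[, 1],
               W_s = kaiming(a, d_f, d_f), b_s = numeric(a),
               u = kaiming(a, 1, a)[, 1])
  if (!is.null(cfg$relevance))
    attn$P <- matrix(0, a, nrow(cfg$relevance$R))
  head <- list(W1 = kaiming(cfg$head_hidden, d_f, d_f),
               b1 = numeric(cfg$head_hidden),
               W2 = kaiming(cfg$class_count, cfg$head_hidden, cfg$head_hidden),
               b2 = numeric(cfg$class_count))
  list(video = video, sensor = sensor, attn = attn, head = head)
}

# -- recurrent primitive ------------------------------------------------------

rnn_bidir_forward <- function(X, cell_fwd, cell_bwd) {
  Hf <- .rnn_forward_cpp(X, cell_fwd$Wx, cell_fwd$Wh, cell_fwd$b)
  Xr <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  Hb <- .rnn_forward_cpp(Xr, cell_bwd$Wx, cell_bwd$Wh, cell_bwd$b)
  Hb <- Hb[rev(seq_len(nrow(Hb))), , drop = FALSE]
  list(H = cbind(Hf, Hb), Hf = Hf, Hb_rev = NULL, X = X)
}

rnn_bidir_backward <- function(fwd_cache, cell_fwd, cell_bwd, dH) {
  X <- fwd_cache$X
  h <- ncol(fwd_cache$Hf)
  T0 <- nrow(X)
  rev_idx <- rev(seq_len(T0))
  dHf <- dH[, seq_len(h), drop = FALSE]
  dHb <- dH[, h + seq_len(h), drop = FALSE]
  gf <- .rnn_backward_cpp(X, fwd_cache$Hf, cell_fwd$Wx, cell_fwd$Wh, dHf)
  Xr <- X[rev_idx, , drop = FALSE]
  Hb_fwdorder <- fwd_cache$H[, h + seq_len(h), drop = FALSE]
  gb <- .rnn_backward_cpp(Xr, Hb_fwdorder[rev_idx, , drop = FALSE],
                          cell_bwd$Wx, cell_bwd$Wh, dHb[rev_idx, , drop = FALSE])
  dX <- gf$dX + gb$dX[rev_idx, , drop = FALSE]
  list(fwd = list(Wx = gf$dWx, Wh = gf$dWh, b = as.vector(gf$db)),
       bwd = list(Wx = gb$dWx, Wh = gb$dWh, b = as.vector(gb$db)),
       dX = dX)
}

#' Encode a video embedding stream
#'
#' Runs the stacked bidirectional recurrent video encoder; one output row per
#' input frame, with `2 * video_hidden` features (forward and backward
#' passes concatenated).  Deterministic given the parameters.
#'
#' @param video_stream Numeric matrix `T_v x d_v`.
#' @param params Parameters from [attnseq_init_params()].
#' @param config The matching [attnseq_config()].
#' @return Numeric matrix `T_v x (2 * video_hidden)`.
#' @export
encode_video <- function(video_stream, params, config) {
  X <- as.matrix(video_stream)
  if (ncol(X) != config$d_v)
    stop("video stream has ", ncol(X), " columns; config expects ",
         config$d_v, call. = FALSE)
  for (layer in params$video$layers)
    X <- rnn_bidir_forward(X, layer$fwd, layer$bwd)$H
  X
}

conv1d_forward <- function(X, W, b) {
  k <- dim(W)[1]
  pad <- (k - 1) %/% 2
  T0 <- nrow(X)
  Xpad <- rbind(matrix(0, pad, ncol(X)), X, matrix(0, pad, ncol(X)))
  Y <- matrix(rep(b, each = T0), T0, length(b))
  for (j in seq_len(k)) {
    Wj <- array(W[j, , ], dim = dim(W)[2:3])
    Y <- Y + Xpad[j:(j + T0 - 1), , drop = FALSE] %*% Wj
  }
  Y
}

conv1d_backward <- function(X, W, dY) {
  k <- dim(W)[1]
  pad <- (k - 1) %/% 2
  T0 <- nrow(X)
  Xpad <- rbind(matrix(0, pad, ncol(X)), X, matrix(0, pad, ncol(X)))
  dW <- array(0, dim = dim(W))
  dXpad <- matrix(0, nrow(Xpad), ncol(X))
  for (j in seq_len(k)) {
    idx <- j:(j + T0 - 1)
    Wj <- array(W[j, , ], dim = dim(W)[2:3])
    dW[j, , ] <- crossprod(Xpad[idx, , drop = FALSE], dY)
    dXpad[idx, ] <- dXpad[idx, ] + dY %*% t(Wj)
  }
  list(dW = dW, db = colSums(dY),
       dX = dXpad[(pad + 1):(pad + T0), , drop = FALSE])
}

sensor_forward_cache <- function(X, params) {
  caches <- list()
  A <- X
  for (i in seq_along(params$sensor$conv)) {
    layer <- params$sensor$conv[[i]]
    pre <- conv1d_forward(A, layer$W, layer$b)
    act <- tanh(pre)
    caches[[i]] <- list(X = A, act = act)
    A <- act
  }
  rc <- rnn_bidir_forward(A, params$sensor$rnn$fwd, params$sensor$rnn$bwd)
  list(conv = caches, rnn = rc, H = rc$H)
}

#' Encode a multichannel sensor stream
#'
#' Runs the sensor branch: a stack of same-length 1-D convolutions (tanh
#' activations) followed by one bidirectional recurrence.  Same-length
#' padding keeps one output row per input time step.
#'
#' @param sensor_stream Numeric matrix `T_s x d_s`.
#' @inheritParams encode_video
#' @return Numeric matrix `T_s x (2 * sensor_hidden)`.
#' @export
encode_sensor <- function(sensor_stream, params, config) {
  X <- as.matrix(sensor_stream)
  if (ncol(X) != config$d_s)
    stop("sensor stream has ", ncol(X), " columns; config expects ",
         config$d_s, call. = FALSE)
  sensor_forward_cache(X, params)$H
}

#' Late-fuse video and sensor embeddings
#'
#' Linearly interpolates the sensor embedding sequence at the video frame
#' timestamps and concatenates it column-wise to the video embedding, so the
#' fused matrix has exactly one row per video frame and the video block is
#' passed through bit-exactly.
#'
#' @param video_emb Numeric matrix `T_v x d_v'`.
#' @param sensor_emb Numeric matrix `T_s' x d_s'`.
#' @param video_rate_hz,sensor_rate_hz Rates of the two embedding sequences.
#' @return Numeric matrix `T_v x (d_v' + d_s')`.
#' @export
fuse_streams <- function(video_emb, sensor_emb, video_rate_hz = 30,
                         sensor_rate_hz = 100) {
  video_emb <- as.matrix(video_emb)
  sensor_emb <- as.matrix(sensor_emb)
  if (nrow(video_emb) == 0 || nrow(sensor_emb) == 0)
    stop("cannot fuse zero-length embeddings", call. = FALSE)
  if (video_rate_hz == sensor_rate_hz &&
      nrow(video_emb) == nrow(sensor_emb))
    return(cbind(video_emb, sensor_emb))
  tv <- (seq_len(nrow(video_emb)) - 1) / video_rate_hz
  iw <- interp_weights(nrow(sensor_emb), sensor_rate_hz, tv)
  cbind(video_emb, interp_apply(sensor_emb, iw))
}
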