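#' Model and training configuration
#'
#' Builds the single configuration object consumed by [attnseq_init_params()],
#' [attnseq_fit()] and the evaluation harness.  Defaults are a desk-scale
#' configuration (bidirectional hidden sizes 16/8, attention dimension 16)
#' that trains on one CPU in seconds to minutes; `full_scale = TRUE` switches
#' to the full-size preset (two-layer 512-unit video encoder, 256-unit sensor
#' encoder, 1536-dimensional fused representation).
#'
#' @param d_v Dimension of the per-frame video embedding stream.
#' @param d_s Number of sensor channels.
#' @param class_count Number of behaviour classes (>= 2).
#' @param video_hidden Hidden units per direction of the video encoder; the
#'   encoder emits `2 * video_hidden` features per frame.
#' @param video_layers Number of stacked bidirectional layers in the video
#'   encoder.
#' @param sensor_conv_channels Integer vector, output channels of each 1-D
#'   convolution layer in the sensor branch.
#' @param sensor_conv_kernel Odd kernel width of the sensor convolutions
#'   (same-length zero padding, stride 1).
#' @param sensor_hidden Hidden units per direction of the sensor encoder.
#' @param attn_dim Attention projection dimension `a`.
#' @param head_hidden Hidden units of the two-layer classifier head.
#' @param pooling Sequence pooling mode: `"hierarchical"` (time-step attention
#'   followed by segment-level attention; the default), `"timestep"` (plain
#'   attention pooling), `"multiscale"` (overlapping attention windows), or
#'   `"mean"` (uniform average, i.e. attention ablated).
#' @param windows List of `c(size, stride)` pairs (in fused time steps) for
#'   multi-scale pooling.  Windows larger than the sequence are clamped to it.
#' @param window_agg How multi-scale window vectors are combined: `"mean"`
#'   (scale-stable default) or `"sum"`.
#' @param n_segments Number of contiguous segments for hierarchical pooling.
#' @param renormalize_segments If `TRUE`, time-step weights are renormalized
#'   within each segment before forming segment vectors; the default keeps the
#'   global weights.
#' @param relevance Optional feature-relevance specification for the
#'   domain-aware score adjustment: a list with `R` (square numeric matrix
#'   acting on the raw video-frame features) as produced by expert knowledge.
#'   `NULL` disables the adjustment.
#' @param lambda_reg Weight of the temporal smoothness penalty on attention
#'   weights.
#' @param weight_decay L2 penalty coefficient.
#' @param decay_scope `"attention"` applies the L2 penalty to the attention
#'   parameters only; `"all"` penalizes every learnable tensor.
#' @param dropout Dropout rate in the classifier head (training only).
#' @param learning_rate Initial Adam learning rate (cosine-annealed).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param clip_norm Global gradient-norm clipping threshold (`Inf` disables).
#' @param ema_decay Exponential-moving-average decay for the evaluation
#'   weights; `0` makes the averaged weights equal the current weights.
#' @param modalities `"both"`, `"video"` or `"sensor"`: which encoder branches
#'   feed the fused representation (single-modality settings ablate fusion).
#' @param sensor_resample_hz Common rate the raw sensor streams are resampled
#'   to before encoding.
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @param full_scale If `TRUE`, override the encoder sizes with the full-size
#'   preset described above.
#' @return A list of class `attnseq_config`.
#' @export
attnseq_config <- function(d_v, d_s, class_count,
                           video_hidden = 16L, video_layers = 1L,
                           sensor_conv_channels = c(16L, 16L),
                           sensor_conv_kernel = 5L,
                           sensor_hidden = 8L,
                           attn_dim = 16L,
                           head_hidden = 32L,
                           pooling = c("hierarchical", "timestep",
                                       "multiscale", "mean"),
                           windows = list(c(16L, 8L), c(32L, 16L)),
                           window_agg = c("mean", "sum"),
                           n_segments = 6L,
                           renormalize_segments = FALSE,
                           relevance = NULL,
                           lambda_reg = 0.01,
                           weight_decay = 0.01,
                           decay_scope = c("attention", "all"),
                           dropout = 0.5,
                           learning_rate = 1e-3,
                           batch_size = 16L,
                           epochs = 60L,
                           clip_norm = 1.0,
                           ema_decay = 0.999,
                           modalities = c("both", "video", "sensor"),
                           sensor_resample_hz = 100,
                           seed = 1L,
                           full_scale = FALSE) {
  pooling <- match.arg(pooling)
  window_agg <- match.arg(window_agg)
  decay_scope <- match.arg(decay_scope)
  modalities <- match.arg(modalities)
  if (isTRUE(full_scale)) {
    video_hidden <- 512L; video_layers <- 2L
    sensor_conv_channels <- c(64L, 64L); sensor_hidden <- 256L
    attn_dim <- 256L; head_hidden <- 512L
  }
  cfg <- list(
    d_v = as.integer(d_v), d_s = as.integer(d_s),
    class_count = as.integer(class_count),
    video_hidden = as.integer(video_hidden),
    video_layers = as.integer(video_layers),
    sensor_conv_channels = as.integer(sensor_conv_channels),
    sensor_conv_kernel = as.integer(sensor_conv_kernel),
    sensor_hidden = as.integer(sensor_hidden),
    attn_dim = as.integer(attn_dim),
    head_hidden = as.integer(head_hidden),
    pooling = pooling,
    windows = unname(lapply(windows, function(w) as.integer(w[1:2]))),
    window_agg = window_agg,
    n_segments = as.integer(n_segments),
    renormalize_segments = isTRUE(renormalize_segments),
    relevance = relevance,
    lambda_reg = lambda_reg,
    weight_decay = weight_decay,
    decay_scope = decay_scope,
    dropout = dropout,
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    epochs = as.integer(epochs),
    clip_norm = clip_norm,
    ema_decay = ema_decay,
    modalities = modalities,
    sensor_resample_hz = sensor_resample_hz,
    seed = as.integer(seed)
  )
  validate_config(cfg)
  structure(cfg, class = "attnseq_config")
}

validate_config <- function(cfg) {
  pos <- c("d_v", "d_s", "class_count", "video_hidden", "video_layers",
           "sensor_hidden", "attn_dim", "head_hidden", "n_segments",
           "batch_size", "epochs", "learning_rate", "sensor_resample_hz")
  for (nm in pos) {
    if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] <= 0))
      stop("config field '", nm, "' must be positive", call. = FALSE)
  }
  if (cfg$class_count < 2) stop("class_count must be >= 2", call. = FALSE)
  if (any(cfg$sensor_conv_channels <= 0))
    stop("sensor_conv_channels must be positive", call. = FALSE)
  if (cfg$sensor_conv_kernel %% 2 != 1)
    stop("sensor_conv_kernel must be odd (same-length padding)", call. = FALSE)
  if (cfg$lambda_reg < 0) stop("lambda_reg must be >= 0", call. = FALSE)
  if (cfg$weight_decay < 0) stop("weight_decay must be >= 0", call. = FALSE)
  if (cfg$dropout < 0 || cfg$dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  if (cfg$ema_decay < 0 || cfg$ema_decay >= 1)
    stop("ema_decay must lie in [0, 1)", call. = FALSE)
  for (w in cfg$windows) {
    if (length(w) != 2 || any(w <= 0))
      stop("each window must be a positive (size, stride) pair", call. = FALSE)
  }
  if (!is.null(cfg$relevance)) {
    R <- cfg$relevance$R
    if (is.null(R) || !is.matrix(R) || nrow(R) != ncol(R))
      stop("relevance$R must be a square matrix", call. = FALSE)
  }
  invisible(cfg)
}

# JSON/YAML round-trips may deliver the window list as a matrix or a list of
# numeric vectors; coerce to a list of integer (size, stride) pairs.
normalize_windows <- function(w) {
  if (is.matrix(w)) w <- split(w, row(w))
  unname(lapply(w, as.integer))
}

normalize_relevance <- function(rel) {
  if (is.null(rel) || is.null(rel$R)) return(rel)
  if (!is.matrix(rel$R))
    rel$R <- do.call(rbind, lapply(rel$R, as.numeric))
  rel
}

# Fused feature dimension implied by the configuration.
fused_dim <- function(cfg) {
  dv2 <- 2L * cfg$video_hidden
  ds2 <- 2L * cfg$sensor_hidden
  switch(cfg$modalities,
         both = dv2 + ds2, video = dv2, sensor = ds2)
}

#' Read or write a configuration file
#'
#' Configurations serialize one-to-one to YAML or JSON (chosen by file
#' extension).  The relevance matrix, if present, is stored as a nested list
#' of rows and restored to a matrix on read.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config An `attnseq_config` object.
#' @return `read_run_config()` returns an `attnseq_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$relevance <- normalize_relevance(raw$relevance)
  raw$windows <- normalize_windows(raw$windows)
  do.call(attnseq_config, raw)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$relevance) && !is.null(x$relevance$R))
    x$relevance$R <- apply(x$relevance$R, 1, as.numeric, simplify = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
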