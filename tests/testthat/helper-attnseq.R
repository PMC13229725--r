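# Shared fixtures: everything is generated in code at test time.

# Minimal attention parameter set for the standalone attention operations.
toy_attn_params <- function(a, d_f, seed = 1, d_raw = NULL) {
  set_global_seed(seed)
  p <- list(W_h = matrix(rnorm(a * d_f), a, d_f), b_h = rnorm(a),
            v = rnorm(a),
            W_s = matrix(rnorm(a * d_f), a, d_f), b_s = rnorm(a),
            u = rnorm(a))
  if (!is.null(d_raw)) p$P <- matrix(rnorm(a * d_raw, sd = 0.3), a, d_raw)
  p
}

# Tiny model configuration (all dims small) used for gradient checks and
# fast training tests.
tiny_config <- function(...) {
  defaults <- list(d_v = 3, d_s = 2, class_count = 3,
                   video_hidden = 2, video_layers = 1,
                   sensor_conv_channels = c(2L, 2L), sensor_conv_kernel = 3,
                   sensor_hidden = 2, attn_dim = 2, head_hidden = 4,
                   n_segments = 2, dropout = 0, lambda_reg = 0.05,
                   weight_decay = 0.02, epochs = 2, batch_size = 4,
                   seed = 1)
  do.call(attnseq_config, utils::modifyList(defaults, list(...)))
}

tiny_spec <- function(...) {
  defaults <- list(n_per_class = 2, class_count = 3, duration_s = 0.4,
                   d_v = 3, d_s = 2, motif_len_s = 0.15, seed = 1)
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

# Central finite differences of the total loss over the flattened
# parameters: the independent oracle for the analytic gradients.
numeric_gradient <- function(batch, params, config, h = 1e-5) {
  pv <- attnseq:::param_flatten(params)
  g <- numeric(length(pv))
  for (i in seq_along(pv)) {
    up <- pv; up[i] <- up[i] + h
    dn <- pv; dn[i] <- dn[i] - h
    fup <- total_loss(batch, attnseq:::param_unflatten(up, params), config)$total
    fdn <- total_loss(batch, attnseq:::param_unflatten(dn, params), config)$total
    g[i] <- (fup - fdn) / (2 * h)
  }
  g
}

max_rel_err <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(floor, abs(a) + abs(b)))
}

random_dataset <- function(n, C = 3, seed = 1, d_v = 2, d_s = 2,
                           Tv = 6, Ts = 10, annotate = FALSE) {
  set_global_seed(seed)
  samples <- lapply(seq_len(n), function(i) {
    sequence_sample(sprintf("r%03d", i),
                    matrix(rnorm(Tv * d_v), Tv, d_v),
                    matrix(rnorm(Ts * d_s), Ts, d_s),
                    video_rate_hz = 30, sensor_rate_hz = 50,
                    label = (i - 1) %% C,
                    annotation = if (annotate) c(0.2, 0.6) * Tv / 30)
  })
  sequence_dataset(samples, C)
}
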