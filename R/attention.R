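# Hierarchical additive attention.
#
# Time-step scores are Bahdanau-style: e_t = v' tanh(W_h h_t + b_h), softmax
# normalized into weights alpha over the sequence.  Three aggregation levels
# sit on top: plain attention pooling (z = sum_t alpha_t h_t), multi-scale
# pooling over overlapping windows, and segment-level attention, where the
# globally weighted rows are summed within contiguous segments
# (s_k = sum_{t in T_k} alpha_t h_t), scored by a second additive attention
# (f_k = u' tanh(W_s s_k + b_s), beta = softmax(f)) and combined into
# r = sum_k beta_k s_k.  An optional domain-relevance term adds P (R x_t)
# inside the tanh, biasing the scores toward expert-flagged raw features;
# with R (or P) zero it reduces exactly to the base score.

#' Additive attention scores per time step
#'
#' Computes `e_t = v' tanh(W_h h_t + b_h + P (R x_t))`, where the
#' domain-relevance term `P (R x_t)` is included only when a relevance
#' matrix is supplied; otherwise the score is the plain additive form.
#'
#' @param H Numeric matrix `T x d_f` of fused features (rows `h_t`).
#' @param params Attention parameter list with `W_h` (`a x d_f`), `b_h`
#'   (`a`), `v` (`a`), and optionally `P` (`a x d_raw`); the `attn`
#'   component of [attnseq_init_params()] has this shape.
#' @param x_raw Optional numeric matrix `T x d_raw` of raw features aligned
#'   with the rows of `H`; required iff `relevance` is supplied.
#' @param relevance Optional square relevance matrix `R` (`d_raw x d_raw`).
#' @return Numeric vector of `T` scores.
#' @export
timestep_scores <- function(H, params, x_raw = NULL, relevance = NULL) {
  H <- as.matrix(H)
  pre <- H %*% t(params$W_h)
  pre <- sweep(pre, 2, params$b_h, "+")
  if (!is.null(relevance)) {
    if (is.null(x_raw))
      stop("x_raw is required when a relevance matrix is supplied",
           call. = FALSE)
    if (is.null(params$P))
      stop("params$P (relevance projection) missing", call. = FALSE)
    pre <- pre + (as.matrix(x_raw) %*% t(relevance)) %*% t(params$P)
  }
  e <- as.vector(tanh(pre) %*% params$v)
  if (!all(is.finite(e))) stop("non-finite attention score", call. = FALSE)
  e
}

#' Numerically stable softmax
#'
#' `alpha_t = exp(e_t) / sum_k exp(e_k)`, computed with max-subtraction;
#' the result is strictly positive and sums to 1.
#'
#' @param scores Finite numeric vector.
#' @return Numeric vector of the same length summing to 1.
#' @export
softmax_normalize <- function(scores) {
  if (length(scores) == 0) stop("empty score vector", call. = FALSE)
  if (!all(is.finite(scores))) stop("non-finite scores", call. = FALSE)
  ex <- exp(scores - max(scores))
  ex / sum(ex)
}

#' Attention-weighted pooling
#'
#' `z = sum_t alpha_t h_t`; with normalized weights, `z` lies in the convex
#' hull of the rows of `H`.
#'
#' @param alpha Numeric weight vector of length `T` (should sum to 1).
#' @param H Numeric matrix `T x d_f`.
#' @return Numeric vector of length `d_f`.
#' @export
pool_weighted <- function(alpha, H) {
  H <- as.matrix(H)
  if (length(alpha) != nrow(H))
    stop("length(alpha) != nrow(H)", call. = FALSE)
  as.vector(crossprod(H, alpha))
}

# Enumerate window start indices (0-based) for a (size, stride) pair on a
# sequence of length T; windows larger than T are clamped to T.
window_starts <- function(T, size, stride) {
  size <- min(size, T)
  starts <- seq(0L, T - size, by = stride)
  list(starts = as.integer(starts), size = as.integer(size))
}

#' Multi-scale windowed attention pooling
#'
#' Divides the sequence into overlapping windows of the configured sizes,
#' computes additive attention within each window, pools each window, and
#' aggregates the per-window vectors — by their mean (scale-stable default)
#' or by their raw sum.
#'
#' @inheritParams timestep_scores
#' @param windows List of `c(size, stride)` pairs in time steps.
#' @param agg `"mean"` or `"sum"` aggregation over window vectors.
#' @return A list with `z` (pooled vector `d_f`), `window_alphas` (list of
#'   per-window normalized weights) and `windows` (data frame of start/size).
#' @export
multiscale_pool <- function(H, windows, params, agg = c("mean", "sum"),
                            x_raw = NULL, relevance = NULL) {
  agg <- match.arg(agg)
  H <- as.matrix(H)
  T0 <- nrow(H)
  zs <- list(); was <- list(); meta <- list()
  for (w in windows) {
    ws <- window_starts(T0, w[1], w[2])
    for (st in ws$starts) {
      idx <- (st + 1):(st + ws$size)
      e <- timestep_scores(H[idx, , drop = FALSE], params,
                           x_raw = if (!is.null(x_raw)) x_raw[idx, , drop = FALSE],
                           relevance = relevance)
      a <- softmax_normalize(e)
      zs[[length(zs) + 1L]] <- pool_weighted(a, H[idx, , drop = FALSE])
      was[[length(was) + 1L]] <- a
      meta[[length(meta) + 1L]] <- c(start = st, size = ws$size)
    }
  }
  if (length(zs) == 0) stop("no window fits the sequence", call. = FALSE)
  Z <- do.call(rbind, zs)
  z <- if (agg == "mean") colMeans(Z) else colSums(Z)
  list(z = z, window_alphas = was,
       windows = as.data.frame(do.call(rbind, meta)))
}

#' Partition a sequence into contiguous segments
#'
#' Returns `K` contiguous, non-overlapping, exhaustive index ranges whose
#' sizes differ by at most one; any remainder is given to the earliest
#' segments.  Ranges are half-open `[start, end)` in 0-based time steps.
#'
#' @param T Sequence length.
#' @param K Number of segments, `1 <= K <= T`.
#' @return Integer matrix `K x 2` with columns `start`, `end`.
#' @export
segment_partition <- function(T, K) {
  T <- as.integer(T); K <- as.integer(K)
  if (K < 1 || K > T)
    stop("need 1 <= K <= T (got K = ", K, ", T = ", T, ")", call. = FALSE)
  sizes <- rep(T %/% K, K) + (seq_len(K) <= T %% K)
  ends <- cumsum(sizes)
  cbind(start = c(0L, ends[-K]), end = ends)
}

#' Segment vectors from globally weighted time steps
#'
#' `s_k = sum_{t in T_k} alpha_t h_t` using the global time-step weights (no
#' per-segment renormalization by default, matching the printed definition;
#' set `renormalize = TRUE` to rescale weights within each segment).  With
#' the global weights, the segment vectors sum exactly to the plain pooled
#' vector.
#'
#' @inheritParams pool_weighted
#' @param partition Matrix from [segment_partition()].
#' @param renormalize Renormalize `alpha` within each segment.
#' @return Numeric matrix `K x d_f` of segment vectors.
#' @export
segment_vectors <- function(alpha, H, partition, renormalize = FALSE) {
  H <- as.matrix(H)
  if (partition[1, "start"] != 0 || partition[nrow(partition), "end"] != nrow(H) ||
      any(partition[-1, "start"] != partition[-nrow(partition), "end"]))
    stop("partition is not contiguous and exhaustive", call. = FALSE)
  K <- nrow(partition)
  S <- matrix(0, K, ncol(H))
  for (k in seq_len(K)) {
    idx <- (partition[k, "start"] + 1):partition[k, "end"]
    a <- alpha[idx]
    if (renormalize) a <- a / sum(a)
    S[k, ] <- crossprod(H[idx, , drop = FALSE], a)
  }
  S
}

#' Segment-level attention
#'
#' Scores each segment vector with a second additive attention,
#' `f_k = u' tanh(W_s s_k + b_s)`, normalizes `beta = softmax(f)` and
#' combines `r = sum_k beta_k s_k`.
#'
#' @param S Numeric matrix `K x d_f` of segment vectors.
#' @param params Attention parameter list with `W_s`, `b_s`, `u`.
#' @return List with `beta` (length `K`, sums to 1), `r` (length `d_f`) and
#'   the raw scores `f`.
#' @export
segment_attention <- function(S, params) {
  S <- as.matrix(S)
  U <- tanh(sweep(S %*% t(params$W_s), 2, params$b_s, "+"))
  f <- as.vector(U %*% params$u)
  beta <- softmax_normalize(f)
  list(beta = beta, r = as.vector(crossprod(S, beta)), f = f)
}

# Full attention stack on a fused sequence: returns the trace (alpha,
# window_alphas, beta, segment vectors, pooled vectors) for one sample under
# the configured pooling mode.  `x_raw` feeds the optional relevance term.
attend_sequence <- function(H, params, config, x_raw = NULL) {
  rel <- if (!is.null(config$relevance)) config$relevance$R
  T0 <- nrow(H)
  if (config$pooling == "mean") {
    alpha <- rep(1 / T0, T0)
    z <- colMeans(H)
    return(list(alpha = alpha, window_alphas = NULL, beta = NULL,
                segment_vectors = NULL, z = z, r = z))
  }
  if (config$pooling == "multiscale") {
    mp <- multiscale_pool(H, config$windows, params, agg = config$window_agg,
                          x_raw = x_raw, relevance = rel)
    # report a global time-step profile as the average of window weights
    prof <- numeric(T0)
    for (i in seq_along(mp$window_alphas)) {
      st <- mp$windows$start[i]
      idx <- (st + 1):(st + mp$windows$size[i])
      prof[idx] <- prof[idx] + mp$window_alphas[[i]]
    }
    prof <- prof / sum(prof)
    return(list(alpha = prof, window_alphas = mp$window_alphas,
                beta = NULL, segment_vectors = NULL, z = mp$z, r = mp$z))
  }
  e <- timestep_scores(H, params, x_raw = x_raw, relevance = rel)
  alpha <- softmax_normalize(e)
  z <- pool_weighted(alpha, H)
  if (config$pooling == "timestep")
    return(list(alpha = alpha, window_alphas = NULL, beta = NULL,
                segment_vectors = NULL, z = z, r = z))
  K <- min(config$n_segments, T0)
  part <- segment_partition(T0, K)
  S <- segment_vectors(alpha, H, part,
                       renormalize = config$renormalize_segments)
  sa <- segment_attention(S, params)
  list(alpha = alpha, window_alphas = NULL, beta = sa$beta,
       segment_vectors = S, z = z, r = sa$r)
}
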