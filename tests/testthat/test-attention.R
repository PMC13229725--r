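test_that("additive scores match hand-evaluated closed forms", {
  # scalar toy: W_h = 1, b_h = 0, v = 2, h = (0, 1) -> e = (0, 2 tanh 1)
  p <- list(W_h = matrix(1, 1, 1), b_h = 0, v = 2)
  e <- timestep_scores(matrix(c(0, 1)), p)
  expect_equal(e, c(0, 2 * tanh(1)), tolerance = 1e-12)
  # zero query vector kills every score
  p0 <- toy_attn_params(3, 4, seed = 1); p0$v <- rep(0, 3)
  expect_equal(timestep_scores(matrix(rnorm(20), 5, 4), p0), rep(0, 5))
})

test_that("relevance adjustment with R = 0 reduces to the base score exactly", {
  set_global_seed(2)
  p <- toy_attn_params(3, 4, seed = 2, d_raw = 2)
  H <- matrix(rnorm(24), 6, 4)
  x_raw <- matrix(rnorm(12), 6, 2)
  base <- timestep_scores(H, p)
  expect_identical(timestep_scores(H, p, x_raw, relevance = matrix(0, 2, 2)),
                   base)
  # and a nonzero R changes the scores
  expect_gt(max(abs(timestep_scores(H, p, x_raw,
                                    relevance = diag(2)) - base)), 0)
  expect_error(timestep_scores(H, p, relevance = diag(2)), "x_raw")
})

test_that("softmax is exact, shift-invariant and stable", {
  expect_equal(softmax_normalize(rep(1.7, 4)), rep(0.25, 4))
  expect_equal(softmax_normalize(c(0, log(3))), c(0.25, 0.75),
               tolerance = 1e-12)
  s <- rnorm(10)
  expect_equal(softmax_normalize(s), softmax_normalize(s + 7.3),
               tolerance = 1e-12)
  expect_equal(sum(softmax_normalize(c(1000, 1001))), 1)  # no overflow
  expect_error(softmax_normalize(numeric(0)), "empty")
  expect_error(softmax_normalize(c(1, NA)), "finite")
})

test_that("weighted pooling selects, averages, and matches hand arithmetic", {
  H <- matrix(rnorm(12), 4, 3)
  onehot <- c(0, 0, 1, 0)
  expect_equal(pool_weighted(onehot, H), H[3, ])
  expect_equal(pool_weighted(rep(0.25, 4), H), colMeans(H))
  expect_equal(pool_weighted(c(0.25, 0.75), rbind(c(2, 0), c(0, 4))),
               c(0.5, 3.0), tolerance = 1e-12)
  expect_error(pool_weighted(c(0.5, 0.5), H), "length")
})

test_that("segment partition is contiguous, exhaustive and balanced", {
  expect_equal(unname(segment_partition(6, 3)),
               cbind(c(0L, 2L, 4L), c(2L, 4L, 6L)))
  expect_equal(unname(segment_partition(7, 3)),
               cbind(c(0L, 3L, 5L), c(3L, 5L, 7L)))  # remainder goes first
  expect_equal(unname(segment_partition(5, 1)), cbind(0L, 5L))
  expect_error(segment_partition(3, 4), "K <= T")
  for (k in 1:30) {
    T0 <- sample(1:60, 1); K <- sample(seq_len(T0), 1)
    part <- segment_partition(T0, K)
    sizes <- part[, "end"] - part[, "start"]
    expect_equal(sum(sizes), T0)
    expect_lte(diff(range(sizes)), 1)
  }
})

test_that("segment vectors use global weights and add up to the pooled vector", {
  H <- rbind(c(1, 2), c(3, -1), c(0, 5))
  alpha <- c(0.5, 0.3, 0.2)
  part <- segment_partition(3, 2)           # [0,2), [2,3)
  S <- segment_vectors(alpha, H, part)
  expect_equal(S[1, ], 0.5 * H[1, ] + 0.3 * H[2, ], tolerance = 1e-12)
  expect_equal(S[2, ], 0.2 * H[3, ], tolerance = 1e-12)
  expect_equal(colSums(S), pool_weighted(alpha, H), tolerance = 1e-12)
  # K = 1 collapses to plain pooling
  expect_equal(segment_vectors(alpha, H, segment_partition(3, 1))[1, ],
               pool_weighted(alpha, H))
  expect_error(segment_vectors(alpha, H, cbind(start = 0L, end = 2L)),
               "exhaustive")
})

test_that("segment attention matches the scalar hand evaluation", {
  p <- list(W_s = matrix(1, 1, 1), b_s = 0, u = 1)
  sa <- segment_attention(matrix(c(0, 10)), p)
  f <- c(0, tanh(10))
  beta <- exp(f) / sum(exp(f))
  expect_equal(sa$f, f, tolerance = 1e-12)
  expect_equal(sa$beta, beta, tolerance = 1e-12)
  expect_equal(sa$r, sum(beta * c(0, 10)), tolerance = 1e-12)
  # zero query -> uniform beta, r = mean of segment vectors
  p2 <- toy_attn_params(2, 3, seed = 3); p2$u <- rep(0, 2)
  S <- matrix(rnorm(12), 4, 3)
  sa2 <- segment_attention(S, p2)
  expect_equal(sa2$beta, rep(0.25, 4))
  expect_equal(sa2$r, colMeans(S))
  # single segment is a fixed point
  sa1 <- segment_attention(S[1, , drop = FALSE], p2)
  expect_equal(sa1$beta, 1)
  expect_equal(sa1$r, S[1, ])
})

test_that("multi-scale pooling reduces, duplicates and averages correctly", {
  set_global_seed(4)
  p <- toy_attn_params(3, 4, seed = 4)
  H <- matrix(rnorm(32), 8, 4)
  # one full-size window: identical to softmax + pooling
  mp <- multiscale_pool(H, list(c(8L, 8L)), p)
  a <- softmax_normalize(timestep_scores(H, p))
  expect_equal(mp$z, pool_weighted(a, H), tolerance = 1e-12)
  # duplicated window: sum doubles, mean is unchanged
  mp_sum <- multiscale_pool(H, list(c(8L, 8L), c(8L, 8L)), p, agg = "sum")
  mp_mean <- multiscale_pool(H, list(c(8L, 8L), c(8L, 8L)), p, agg = "mean")
  expect_equal(mp_sum$z, 2 * mp$z, tolerance = 1e-12)
  expect_equal(mp_mean$z, mp$z, tolerance = 1e-12)
  # disjoint halves of a constant sequence return that constant (mean mode)
  Hc <- matrix(rep(c(1, -2, 0.5, 3), each = 8), 8, 4)
  mpc <- multiscale_pool(Hc, list(c(4L, 4L)), p, agg = "mean")
  expect_equal(mpc$z, Hc[1, ], tolerance = 1e-12)
  # oversized windows are clamped to the sequence
  mp_big <- multiscale_pool(H, list(c(100L, 1L)), p)
  expect_equal(mp_big$windows$size, 8)
})

test_that("every attention weight vector is normalized (property sweep)", {
  for (k in 1:60) {
    set_global_seed(500 + k)
    T0 <- sample(2:50, 1); d_f <- sample(2:6, 1); a <- sample(2:4, 1)
    p <- toy_attn_params(a, d_f, seed = 500 + k)
    H <- matrix(rnorm(T0 * d_f, sd = 3), T0, d_f)
    alpha <- softmax_normalize(timestep_scores(H, p))
    expect_lt(abs(sum(alpha) - 1), 1e-12)
    expect_true(all(alpha > 0))
    mp <- multiscale_pool(H, list(c(min(7L, T0), 3L)), p)
    for (wa in mp$window_alphas) expect_lt(abs(sum(wa) - 1), 1e-12)
    K <- sample(seq_len(T0), 1)
    S <- segment_vectors(alpha, H, segment_partition(T0, K))
    expect_lt(abs(sum(segment_attention(S, p)$beta) - 1), 1e-12)
  }
})

test_that("permuting time steps permutes the weights identically", {
  set_global_seed(6)
  p <- toy_attn_params(3, 5, seed = 6)
  H <- matrix(rnorm(40), 8, 5)
  perm <- sample(8)
  a1 <- softmax_normalize(timestep_scores(H, p))
  a2 <- softmax_normalize(timestep_scores(H[perm, ], p))
  expect_equal(a2, a1[perm], tolerance = 1e-12)
})

test_that("hierarchical, multiscale and plain pooling agree in the degenerate case", {
  # K_seg = 1 segment and a single full-size window all reduce to Eq-15
  # pooling of the globally softmaxed scores
  set_global_seed(7)
  p <- toy_attn_params(3, 4, seed = 7)
  H <- matrix(rnorm(36), 9, 4)
  alpha <- softmax_normalize(timestep_scores(H, p))
  z_plain <- pool_weighted(alpha, H)
  z_multi <- multiscale_pool(H, list(c(9L, 9L)), p)$z
  S <- segment_vectors(alpha, H, segment_partition(9, 1))
  z_seg <- segment_attention(S, p)$r
  expect_equal(z_multi, z_plain, tolerance = 1e-9)
  expect_equal(z_seg, z_plain, tolerance = 1e-9)
})
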