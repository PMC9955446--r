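test_that("Bernoulli weight masks hit the degenerate limits and the sampling rate", {
  rng <- rng_stream(1)
  expect_equal(sample_weight_mask(c(3, 4), 0, rng), matrix(1, 3, 4))
  expect_equal(sample_weight_mask(c(3, 4), 1, rng), matrix(0, 3, 4))
  m <- sample_weight_mask(10000, 0.3, rng_stream(42))
  drop_frac <- mean(m == 0)
  expect_lt(abs(drop_frac - 0.3), 4 * sqrt(0.3 * 0.7 / 10000))
  # reproducible given the seed
  expect_identical(m, sample_weight_mask(10000, 0.3, rng_stream(42)))
  # per-weight rho array is honoured elementwise
  rho <- c(rep(0, 500), rep(1, 500))
  m2 <- sample_weight_mask(1000, rho, rng)
  expect_equal(m2[501:1000], rep(0, 500))
  expect_equal(m2[1:500], rep(1, 500))
})

test_that("node masks are Bernoulli keep indicators", {
  rng <- rng_stream(3)
  expect_equal(sample_node_mask(7, 0, rng), rep(1, 7))
  expect_equal(sample_node_mask(7, 1, rng), rep(0, 7))
  kept <- mean(sample_node_mask(10000, 0.5, rng_stream(9)))
  expect_lt(abs(kept - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("mask parameters outside [0,1] and shape mismatches are rejected", {
  rng <- rng_stream(1)
  expect_error(sample_weight_mask(c(2, 2), 1.2, rng), "\\[0, 1\\]")
  expect_error(sample_weight_mask(c(2, 2), -0.1, rng), "\\[0, 1\\]")
  expect_error(sample_weight_mask(c(2, 2), rep(0.5, 3), rng), "shape")
  expect_error(sample_node_mask(5, 2, rng), "\\[0, 1\\]")
  expect_error(weak_weight_mask(c(1, NaN), weak_absolute(0.1)), "finite")
  expect_error(dropweak_spec(weight_drop_prob = -1), "\\[0, 1\\]")
})

test_that("weak-weight masking zeroes low-magnitude weights deterministically", {
  expect_equal(weak_weight_mask(c(0, 0.2, -0.3), weak_absolute(0)),
               c(1, 1, 1))  # strict inequality keeps exact zeros
  expect_equal(weak_weight_mask(c(1.0, -0.01, 0.5), weak_absolute(0.1)),
               c(1, 0, 1))
  expect_equal(weak_weight_mask(c(3, 1, 2), weak_quantile(1 / 3)),
               c(1, 0, 1))
  # idempotent / deterministic
  w <- matrix(rnorm(20), 4, 5)
  m1 <- weak_weight_mask(w, weak_quantile(0.25))
  expect_identical(m1, weak_weight_mask(w, weak_quantile(0.25)))
  expect_equal(sum(m1 == 0), floor(0.25 * 20))
  # quantile ties broken by flat index: first of the tied entries dropped
  expect_equal(weak_weight_mask(c(0.5, 0.5, 1), weak_quantile(1 / 3)),
               c(0, 1, 1))
})

test_that("apply_dropweak reduces to the dense affine map with all-off masks", {
  spec <- dw_off()
  W <- matrix(rnorm(12), 3, 4); x <- matrix(rnorm(8), 4, 2); b <- rnorm(3)
  mk <- sample_mask_set(W, spec, rng_stream(1))
  expect_identical(apply_dropweak(W, x, mk, spec, bias = b), W %*% x + b)
})

test_that("a dropped node zeroes its output coordinate exactly", {
  spec <- dropweak_spec(node_drop_prob = 0.5, weight_drop_prob = 0,
                        weak_rule = weak_absolute(0), scale_mode = "none")
  W <- matrix(rnorm(12), 3, 4); x <- matrix(rnorm(4), 4, 1)
  mk <- sample_mask_set(W, spec, rng_stream(2))
  mk$node_mask <- c(1, 0, 1)
  out <- apply_dropweak(W, x, mk, spec)
  expect_identical(out[2, 1], 0)
  expect_equal(out[c(1, 3), 1], (W %*% x)[c(1, 3), 1])
})

test_that("inverted scaling makes the masked pass unbiased for the dense pass", {
  spec <- dropweak_spec(node_drop_prob = 0, weight_drop_prob = 0.4,
                        weak_rule = weak_absolute(0),
                        scale_mode = "inverted")
  set.seed(11)
  W <- matrix(rnorm(6), 2, 3); x <- c(0.7, -1.2, 0.4)
  dense <- as.vector(W %*% x)
  rng <- rng_stream(17)
  M <- 20000
  draws <- matrix(NA_real_, M, 2)
  for (i in seq_len(M)) {
    mk <- sample_mask_set(W, spec, rng)
    draws[i, ] <- apply_dropweak(W, x, mk, spec)
  }
  se <- apply(draws, 2, sd) / sqrt(M)
  expect_true(all(abs(colMeans(draws) - dense) < 4 * se))
})

test_that("mc_activation_estimate averages masked passes and converges", {
  # all mechanisms off: every sample identical, mean equals a single pass
  spec_off <- dropweak_spec(0, 0, weak_absolute(0), "inverted")
  W <- matrix(rnorm(6), 2, 3); x <- c(1, 2, 3)
  one <- apply_dropweak(W, x, sample_mask_set(W, spec_off, rng_stream(1)),
                        spec_off)
  expect_equal(mc_activation_estimate(W, x, spec_off, 7, rng_stream(4)),
               one)
  # M = 1 equals one apply_dropweak call on the same stream
  spec <- dropweak_spec(0.2, 0.3, weak_absolute(0), "inverted")
  est1 <- mc_activation_estimate(W, x, spec, 1, rng_stream(9))
  rng <- rng_stream(9)
  expect_identical(est1,
                   apply_dropweak(W, x, sample_mask_set(W, spec, rng), spec))
  # M = 5000, rho = 0.3: within 4 SE of the dense output; the oracle
  # replays the same stream to recover the per-draw spread
  spec3 <- dropweak_spec(0, 0.3, weak_absolute(0), "inverted")
  est <- mc_activation_estimate(W, x, spec3, 5000, rng_stream(21))
  rng <- rng_stream(21)
  draws <- matrix(NA_real_, 5000, 2)
  for (i in 1:5000)
    draws[i, ] <- apply_dropweak(W, x, sample_mask_set(W, spec3, rng),
                                 spec3)
  expect_equal(as.vector(est), colMeans(draws))  # same stream, same average
  se <- apply(draws, 2, sd) / sqrt(5000)
  expect_true(all(abs(as.vector(est) - as.vector(W %*% x)) < 4 * se))
  expect_error(mc_activation_estimate(W, x, spec3, 0, rng), ">= 1")
})

test_that("DropWeak collapses to plain dropout / DropConnect in the limits", {
  W <- matrix(rnorm(20), 4, 5); x <- matrix(rnorm(15), 5, 3)
  # weight_drop_prob = 0, tau = 0  ->  node dropout on the same stream
  p <- 0.3
  spec <- dropweak_spec(node_drop_prob = p, weight_drop_prob = 0,
                        weak_rule = weak_absolute(0),
                        scale_mode = "inverted")
  got <- apply_dropweak(W, x, sample_mask_set(W, spec, rng_stream(33)),
                        spec)
  rng <- rng_stream(33)
  stream_eval(rng, runif(length(W)))          # weight-mask slot (all kept)
  keep <- stream_eval(rng, as.numeric(runif(4) >= p))
  dropout_ref <- (W %*% x) * (keep / (1 - p)) # independent dropout
  expect_equal(got, dropout_ref)
  # node_drop_prob = 0, tau = 0  ->  DropConnect on the same stream
  rho <- 0.4
  spec2 <- dropweak_spec(node_drop_prob = 0, weight_drop_prob = rho,
                         weak_rule = weak_absolute(0),
                         scale_mode = "inverted")
  got2 <- apply_dropweak(W, x, sample_mask_set(W, spec2, rng_stream(34)),
                         spec2)
  rng <- rng_stream(34)
  wm <- stream_eval(rng, matrix(as.numeric(runif(length(W)) >= rho), 4, 5))
  dropconnect_ref <- ((W * wm) / (1 - rho)) %*% x
  expect_equal(got2, dropconnect_ref)
})

test_that("the magnitude-inverse schedule ranks drop probability against |w|", {
  w <- c(0.01, -2, 0.5, -0.1)
  rho <- rho_magnitude_schedule(w, rho_max = 0.6)
  expect_equal(rho, c(0.6, 0, 0.2, 0.4))   # smallest |w| -> rho_max
  expect_true(all(rho >= 0 & rho <= 0.6))
  wm <- matrix(rnorm(12), 3, 4)
  rr <- rho_magnitude_schedule(wm, 0.3)
  expect_equal(dim(rr), dim(wm))
  # usable directly as a per-weight rho array
  mk <- sample_weight_mask(dim(wm), rr, rng_stream(2))
  expect_equal(dim(mk), dim(wm))
  # the largest-magnitude weight is never dropped (rho = 0)
  expect_equal(mk[which.max(abs(wm))], 1)
})

test_that("masking never mutates the master weights", {
  spec <- dropweak_spec(0.3, 0.3, weak_quantile(0.2), "inverted")
  W <- matrix(rnorm(24), 4, 6)
  W_copy <- W + 0
  rng <- rng_stream(5)
  for (i in 1:20) {
    mk <- sample_mask_set(W, spec, rng)
    invisible(apply_dropweak(W, matrix(rnorm(12), 6, 2), mk, spec))
  }
  expect_identical(W, W_copy)
})

test_that("conv-shaped weights mask per kernel element with channel node masks", {
  spec <- dw_off()
  w <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  mk <- sample_mask_set(w, spec, rng_stream(1))
  expect_length(mk$node_mask, 4)          # one per output channel
  expect_equal(dim(mk$weight_mask), dim(w))
  out <- apply_dropweak(w, x, mk, spec)
  expect_equal(dim(out), c(8, 8, 4, 3))
  # zeroing channel 2 zeroes that output channel only
  mk$node_mask <- c(1, 0, 1, 1)
  out2 <- apply_dropweak(w, x, mk, spec)
  expect_true(all(out2[, , 2, ] == 0))
  expect_equal(out2[, , c(1, 3, 4), ], out[, , c(1, 3, 4), ])
})
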