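test_that("entropy matches the closed form and rejects non-distributions", {
  expect_equal(entropy_nats(c(0.5, 0.5)), log(2))
  expect_equal(entropy_nats(c(1, 0)), 0)
  expect_equal(entropy_nats(c(0.25, 0.75)),
               -0.25 * log(0.25) - 0.75 * log(0.75))
  expect_error(entropy_nats(c(0.7, 0.7)), "simplex")
  expect_error(entropy_nats(c(-0.2, 1.2)), "simplex")
})

test_that("predictive mean averages passes and stays on the simplex", {
  p <- c(0.2, 0.8)
  mc <- new_mc_set(array(rep(p, each = 3 * 2), c(3, 2, 2)))
  expect_equal(predictive_mean(mc), matrix(p, 2, 2, byrow = TRUE))
  mc2 <- new_mc_set(array(c(1, 0, 0, 1), c(2, 1, 2)))
  expect_equal(predictive_mean(mc2), matrix(c(0.5, 0.5), 1, 2))
  set.seed(1)
  probs <- array(NA_real_, c(10, 6, 4))
  for (t in 1:10) probs[t, , ] <- random_simplex(6, 4)
  pm <- predictive_mean(new_mc_set(probs))
  expect_equal(rowSums(pm), rep(1, 6), tolerance = 1e-9)
})

test_that("uncertainty decomposition matches the trivial cases", {
  p <- c(0.3, 0.7)
  mc <- new_mc_set(array(rep(p, each = 5), c(5, 1, 2)))
  rep1 <- decompose_uncertainty(mc)
  expect_equal(rep1$epistemic, 0, tolerance = 1e-12)
  expect_equal(rep1$aleatoric, entropy_nats(p), tolerance = 1e-12)
  # pure disagreement: two one-hot passes
  mc2 <- new_mc_set(array(c(1, 0, 0, 1), c(2, 1, 2)))
  rep2 <- decompose_uncertainty(mc2)
  expect_equal(rep2$predictive_entropy, log(2), tolerance = 1e-12)
  expect_equal(rep2$aleatoric, 0, tolerance = 1e-12)
  expect_equal(rep2$epistemic, log(2), tolerance = 1e-12)
})

test_that("decomposition agrees with an independent brute-force implementation", {
  set.seed(7)
  C <- 3
  probs <- array(NA_real_, c(200, 4, C))
  for (t in 1:200) probs[t, , ] <- random_simplex(4, C)
  mc <- new_mc_set(probs)
  rep <- decompose_uncertainty(mc)
  for (n in 1:4) {
    o <- oracle_decompose(probs[, n, ])
    expect_equal(rep$predictive_entropy[n], o$H, tolerance = 1e-12)
    expect_equal(rep$aleatoric[n], o$A, tolerance = 1e-12)
    expect_equal(rep$epistemic[n], o$MI, tolerance = 1e-12)
  }
  # identity, nonnegativity and entropy bounds
  expect_equal(rep$epistemic_raw,
               rep$predictive_entropy - rep$aleatoric, tolerance = 1e-14)
  expect_true(all(rep$epistemic_raw >= -1e-9))
  expect_true(all(rep$predictive_entropy <= log(C) + 1e-12))
  expect_true(all(rep$aleatoric <= log(C) + 1e-12))
  expect_true(all(rep$predictive_entropy >= 0 & rep$aleatoric >= 0))
})

test_that("jackknife MI matches hand enumeration and vanishes on agreement", {
  # all passes identical -> every leave-one-out equals the full value
  p <- c(0.6, 0.4)
  mc <- new_mc_set(array(rep(p, each = 6), c(6, 1, 2)))
  expect_equal(bias_corrected_mi(mc), 0, tolerance = 1e-12)
  # T = 3 hand-sized case, enumerated leave-one-out subsets
  passes <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.7, 0.3))
  mc3 <- new_mc_set(array(passes, c(3, 1, 2)))
  expect_equal(bias_corrected_mi(mc3), oracle_jackknife_mi(passes),
               tolerance = 1e-12)
  expect_error(bias_corrected_mi(new_mc_set(array(c(1, 0), c(1, 1, 2)))),
               "T >= 3")
  # a larger random instance, per-sample
  set.seed(3)
  probs <- array(NA_real_, c(9, 3, 2))
  for (t in 1:9) probs[t, , ] <- random_simplex(3, 2)
  got <- bias_corrected_mi(new_mc_set(probs))
  for (n in 1:3)
    expect_equal(got[n], oracle_jackknife_mi(probs[, n, ]),
                 tolerance = 1e-12)
})

test_that("the jackknife reduces the entropy estimator's finite-sample bias", {
  # one-hot passes from a known 2-class categorical, T = 25
  p_true <- c(0.3, 0.7)
  H_true <- oracle_entropy(p_true)
  set.seed(123)
  Tn <- 25
  plug <- numeric(2000); jack <- numeric(2000)
  for (r in 1:2000) {
    k <- rbinom(1, Tn, p_true[1])
    passes <- rbind(matrix(rep(c(1, 0), k), ncol = 2, byrow = TRUE),
                    matrix(rep(c(0, 1), Tn - k), ncol = 2, byrow = TRUE))
    plug[r] <- entropy_nats(colMeans(passes))
    jack[r] <- jackknife_entropy(passes)
  }
  expect_lt(abs(mean(jack) - H_true), abs(mean(plug) - H_true))
})

test_that("PH values are the row maxima and permutation-invariant", {
  expect_equal(ph_values(matrix(c(0.5, 0.5), 1)), 0.5)
  expect_equal(ph_values(matrix(c(0.1, 0.9), 1)), 0.9)
  pm <- random_simplex(5, 4)
  perm <- pm[, c(3, 1, 4, 2)]
  expect_equal(ph_values(pm), ph_values(perm))
  expect_true(all(ph_values(pm) >= 1 / 4 & ph_values(pm) <= 1))
})

test_that("mc_predict is deterministic given the seed and collapses when masks are off", {
  cfg <- baresnet_config(input_size = 16, dropweak = dw_off(),
                         dropout_prob = 0)
  m <- build_baresnet(cfg, seed = 6)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  mc <- mc_predict(m, x, T = 4, seed = 2)
  for (t in 2:4) expect_equal(mc$probs[t, , ], mc$probs[1, , ])
  # stochastic model: reproducible, and T = 1 equals one stochastic pass
  # on the same substream
  fix <- small_trained_model()
  xb <- fix$data$images[, , 1:5]
  mc1 <- mc_predict(fix$model, xb, T = 3, seed = 11)
  mc2 <- mc_predict(fix$model, xb, T = 3, seed = 11)
  expect_identical(mc1$probs, mc2$probs)
  one <- mc_predict(fix$model, xb, T = 1, seed = 11)
  rng <- rng_stream(substream_seed(11, "mc_masks"))
  ref <- baresnet_forward(fix$model, xb, stochastic = TRUE, rng = rng)
  expect_equal(one$probs[1, , ], ref)
  expect_error(mc_predict(fix$model, xb, T = 0), ">= 1")
})

test_that("uncertainty CSV has the documented columns", {
  fix <- small_trained_model()
  mc <- mc_predict(fix$model, fix$data$images[, , 1:6], T = 5, seed = 3)
  rep <- decompose_uncertainty(mc)
  path <- tempfile(fileext = ".csv")
  df <- write_uncertainty_csv(rep, path)
  got <- utils::read.csv(path)
  expect_equal(names(got),
               c("sample_id", "pred_class", "ph", "pred_entropy",
                 "aleatoric", "epistemic", "epistemic_bc"))
  expect_equal(nrow(got), 6)
  unlink(path)
})
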