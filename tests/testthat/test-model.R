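test_that("forward emits probability rows on the simplex", {
  m <- build_baresnet(baresnet_config(), seed = 1)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- baresnet_forward(m, x)
  expect_equal(dim(p), c(3, 2))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
})

test_that("deterministic passes are repeatable and seed-invariant; no-op masks match", {
  cfg <- baresnet_config(input_size = 16, dropweak = dw_off(),
                         dropout_prob = 0)
  m <- build_baresnet(cfg, seed = 2)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  expect_identical(baresnet_forward(m, x), baresnet_forward(m, x))
  # stochastic pass with every mechanism off equals the deterministic pass
  expect_equal(baresnet_forward(m, x, stochastic = TRUE,
                                rng = rng_stream(99)),
               baresnet_forward(m, x))
})

test_that("wrong spatial size is rejected, never silently resized", {
  m <- build_baresnet(baresnet_config(input_size = 64), seed = 1)
  expect_error(baresnet_forward(m, array(0.5, c(32, 32, 1))), "64x64")
})

test_that("parameter count matches the closed-form layer sum", {
  cfg <- baresnet_config(input_size = 16, channels = c(4, 8))
  m <- build_baresnet(cfg, seed = 1)
  hand <- (3 * 3 * 1 * 4 + 4) +      # stem conv
    2 * (3 * 3 * 4 * 4 + 4) +        # block-1 convs
    (3 * 3 * 4 * 8 + 8) +            # transition conv
    2 * (3 * 3 * 8 * 8 + 8) +        # block-2 convs
    (8 * 2 + 2)                      # fully connected
  expect_equal(param_count(m), hand)
})

test_that("a vanishing learning rate leaves the weights unchanged", {
  fix <- small_trained_model()
  ds <- fix$data
  m0 <- build_baresnet(small_config(), seed = 3)
  tc <- train_config(learning_rate = 1e-30, epochs = 1, batch_size = 32,
                     seed = 4)
  m1 <- train_baresnet(m0, ds, tc)
  for (nm in names(m0$weights))
    expect_equal(m1$weights[[nm]]$w, m0$weights[[nm]]$w,
                 tolerance = 1e-12)
})

test_that("training is bit-reproducible under a fixed seed", {
  ds <- generate_dataset(small_spec(n = 120, seed = 55))
  tc <- train_config(epochs = 2, batch_size = 32, seed = 13)
  m1 <- train_baresnet(build_baresnet(small_config(), seed = 8), ds, tc)
  m2 <- train_baresnet(build_baresnet(small_config(), seed = 8), ds, tc)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$weights, m2$weights)
})

test_that("training reduces the loss on a separable synthetic task", {
  fix <- small_trained_model()
  log <- fix$model$training_log
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  expect_gt(max(log$val_acc), 0.8)
})

test_that("checkpoint round-trip reproduces bit-identical behaviour", {
  fix <- small_trained_model()
  path <- tempfile(fileext = ".rds")
  save_model(fix$model, path)
  m2 <- load_model(path)
  expect_identical(m2$weights, fix$model$weights)
  x <- fix$data$images[, , 1:4]
  expect_identical(baresnet_forward(m2, x),
                   baresnet_forward(fix$model, x))
  unlink(path)
})

test_that("empty splits are rejected", {
  ds <- generate_dataset(small_spec(n = 40, seed = 9))
  ds$split <- rep("train", 40)   # no validation samples
  expect_error(train_baresnet(build_baresnet(small_config(), seed = 1),
                              ds, train_config(epochs = 1)),
               "split")
})

test_that("an exploding learning rate raises a divergence error with a checkpoint", {
  ds <- generate_dataset(small_spec(n = 60, seed = 77))
  err <- tryCatch(
    train_baresnet(build_baresnet(small_config(), seed = 1), ds,
                   train_config(learning_rate = 1e80, epochs = 5,
                                batch_size = 16, seed = 2)),
    dropweakuq_divergence = function(e) e)
  expect_s3_class(err, "dropweakuq_divergence")
  expect_s3_class(err$model, "baresnet")   # last good checkpoint attached
})

test_that("augmentation is a toggle that leaves training runnable", {
  ds <- generate_dataset(small_spec(n = 60, seed = 31))
  m <- train_baresnet(build_baresnet(small_config(), seed = 1), ds,
                      train_config(epochs = 1, batch_size = 16, seed = 3,
                                   augmentation = TRUE))
  expect_s3_class(m, "baresnet")
  expect_equal(nrow(m$training_log), 1)
  # rotation keeps the image range and shape
  img <- matrix(runif(256), 16, 16)
  rot <- dropweakuq:::rotate_nn(img, 10)
  expect_equal(dim(rot), c(16, 16))
  expect_true(all(rot >= 0 & rot <= 1))
  expect_equal(dropweakuq:::rotate_nn(img, 0), img)
})

test_that("DropWeak narrows the train-test accuracy gap under label noise", {
  # 20% label noise; median over 5 seeds of the generalization gap with
  # the full masking scheme vs no masking at all
  gaps <- vapply(1:5, function(s) {
    sp <- small_spec(n = 240, seed = 200 + s)
    sp$label_noise_rate <- 0.2
    ds <- generate_dataset(sp)
    tc <- train_config(epochs = 8, batch_size = 32, seed = 300 + s)
    gap_for <- function(cfg) {
      m <- train_baresnet(build_baresnet(cfg, seed = s), ds, tc)
      acc <- function(idx)
        mean((max.col(baresnet_forward(m, ds$images[, , idx])) - 1L) ==
               ds$labels[idx])
      acc(which(m$split == "train")) - acc(which(m$split == "test"))
    }
    masked <- gap_for(small_config())
    unmasked <- gap_for(baresnet_config(input_size = 16, channels = c(8, 16),
                                        dropweak = dw_off(),
                                        dropout_prob = 0))
    masked - unmasked
  }, 0)
  expect_lte(median(gaps), 0)
})

test_that("naive-Bayes fusion head obeys its algebra and matches e1071", {
  fix <- small_trained_model()
  m <- naive_bayes_head_fit(fix$model, fix$data)
  x <- fix$data$images[, , 1:8]
  fused <- nb_fused_predict(m, x)
  expect_equal(rowSums(fused), rep(1, 8), tolerance = 1e-9)
  # uniform NB posterior: fused prediction equals the SoftMax prediction
  m_unif <- m
  m_unif$nb_head$mean[] <- 0; m_unif$nb_head$sd[] <- 1
  m_unif$nb_head$prior[] <- 0.5
  expect_equal(nb_fused_predict(m_unif, x), baresnet_forward(m, x),
               tolerance = 1e-9)
  skip_if_not_installed("e1071")
  feats <- dropweakuq:::penultimate_features(m, fix$data$images)
  idx <- which(m$split == "train")
  df <- data.frame(feats[idx, ])
  nb <- e1071::naiveBayes(df, factor(fix$data$labels[idx]))
  ref <- predict(nb, data.frame(feats[1:8, , drop = FALSE]), type = "raw")
  mine <- dropweakuq:::nb_posterior(m$nb_head, feats[1:8, , drop = FALSE])
  expect_equal(unname(mine), unname(ref), tolerance = 1e-6)
})
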