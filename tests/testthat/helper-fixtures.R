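# Shared fixtures. Trained models are expensive, so they are built lazily
# once per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

# small phantom spec that trains in seconds (16x16 images)
small_spec <- function(n = 300, seed = 101) {
  synthetic_spec(n_images = n, image_size = 16,
                 benign_diameter = c(3, 5), malignant_diameter = c(8, 12),
                 label_noise_rate = 0.05, seed = seed)
}

small_config <- function() {
  baresnet_config(input_size = 16, channels = c(8, 16))
}

# a quickly trained 16x16 model shared across test files
small_trained_model <- function() {
  if (is.null(.fixtures$small_model)) {
    ds <- generate_dataset(small_spec())
    m <- build_baresnet(small_config(), seed = 5)
    m <- train_baresnet(m, ds, train_config(epochs = 8, batch_size = 32,
                                            seed = 7))
    .fixtures$small_model <- m
    .fixtures$small_data <- ds
  }
  list(model = .fixtures$small_model, data = .fixtures$small_data)
}

# a desk-scale study run on the default 64x64 spec: train once per seed
# and cache (train split 80%, 20 epochs)
study_run <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(.fixtures[[key]])) {
    ds <- generate_dataset(synthetic_spec(seed = seed))
    m <- build_baresnet(baresnet_config(), seed = seed)
    m <- train_baresnet(m, ds, train_config(epochs = 20, batch_size = 16,
                                            seed = seed))
    .fixtures[[key]] <- list(model = m, data = ds)
  }
  .fixtures[[key]]
}

# an all-off DropWeak spec: no node drops, no weight drops, no weak rule
dw_off <- function() {
  dropweak_spec(node_drop_prob = 0, weight_drop_prob = 0,
                weak_rule = weak_absolute(0), scale_mode = "none")
}
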