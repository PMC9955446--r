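#' Default run configuration
#'
#' Nested configuration consumed by the pipeline stages and the command
#' line. Keys mirror the module parameters: `data.*` (synthetic spec or a
#' manifest path), `dropweak.*`, `model.*`, `train.*`, `uq.*`, `eval.*`,
#' plus the root `seed`. Unknown keys in a user config are rejected.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    data = list(source = "synthetic", manifest = NULL, n_images = 2000L,
                image_size = 64L, label_noise_rate = 0.05,
                class_balance = 0.5),
    dropweak = list(node_drop_prob = 0.1, weight_drop_prob = 0.1,
                    weak_rule = list(type = "quantile", value = 0.1),
                    scale_mode = "inverted"),
    model = list(channels = c(8L, 16L), n_classes = 2L,
                 dropout_prob = 0.1, nb_head = FALSE),
    train = list(learning_rate = 1e-3, lr_factor = 0.2, patience = 10L,
                 batch_size = 16L, epochs = 20L,
                 split = c(0.8, 0.1, 0.1), augmentation = FALSE),
    uq = list(mc_samples = 25L),
    eval = list(k = 9L, thresholds = c(0.3, 0.5), mode = "entropy"))
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste(path, key, sep = ".")
    if (!key %in% names(defaults))
      stop(sprintf("unknown config key: %s", full), call. = FALSE)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("config key %s must be a mapping", full),
             call. = FALSE)
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration (YAML or JSON)
#'
#' User keys override the defaults; unknown keys raise an error naming the
#' key path.
#'
#' @param path `.yaml`/`.yml` or `.json` file, or `NULL` for defaults.
#' @return validated nested configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  merge_config(cfg, user)
}

cfg_dropweak <- function(cfg) {
  wr <- cfg$dropweak$weak_rule
  rule <- if (identical(wr$type, "absolute")) weak_absolute(wr$value)
  else weak_quantile(wr$value)
  dropweak_spec(cfg$dropweak$node_drop_prob, cfg$dropweak$weight_drop_prob,
                rule, cfg$dropweak$scale_mode)
}

cfg_model <- function(cfg) {
  baresnet_config(input_size = cfg$data$image_size,
                  channels = cfg$model$channels,
                  n_classes = cfg$model$n_classes,
                  dropweak = cfg_dropweak(cfg),
                  dropout_prob = cfg$model$dropout_prob,
                  nb_head = cfg$model$nb_head)
}

cfg_train <- function(cfg) {
  train_config(learning_rate = cfg$train$learning_rate,
               lr_factor = cfg$train$lr_factor,
               patience = cfg$train$patience,
               batch_size = cfg$train$batch_size,
               epochs = cfg$train$epochs, seed = cfg$seed,
               split = cfg$train$split,
               augmentation = cfg$train$augmentation)
}

cfg_synthetic <- function(cfg) {
  synthetic_spec(n_images = cfg$data$n_images,
                 image_size = cfg$data$image_size,
                 label_noise_rate = cfg$data$label_noise_rate,
                 class_balance = cfg$data$class_balance, seed = cfg$seed)
}

cfg_dataset <- function(cfg) {
  if (identical(cfg$data$source, "synthetic")) {
    ds <- generate_dataset(cfg_synthetic(cfg))
    ds$split <- make_split(ds$labels, cfg$train$split, cfg$seed)
    ds
  } else {
    read_image_manifest(cfg$data$manifest)
  }
}

echo_run <- function(cfg, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  log_line(out, sprintf("dropweakuq %s seed=%s",
                        as.character(utils::packageVersion("dropweakuq")),
                        cfg$seed))
  invisible(out)
}

log_line <- function(out, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = file.path(out, "run.log"), append = TRUE)
}

# ---- dataset I/O --------------------------------------------------------

#' Write a dataset as 8-bit grayscale PNGs with a CSV manifest
#'
#' Manifest columns: `path,label,clean_label,split,fold` (split/fold when
#' present); the generating spec is echoed to `spec.json`.
#'
#' @param dataset a `dw_dataset`.
#' @param dir output directory.
#' @return manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  n <- dim(dataset$images)[3L]
  paths <- file.path("images", sprintf("img_%05d.png", seq_len(n)))
  for (i in seq_len(n))
    png::writePNG(dataset$images[, , i], file.path(dir, paths[i]))
  man <- data.frame(path = paths, label = dataset$labels)
  if (!is.null(dataset$clean_labels)) man$clean_label <- dataset$clean_labels
  if (!is.null(dataset$split)) man$split <- dataset$split
  if (!is.null(dataset$fold)) man$fold <- dataset$fold
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE)
  if (!is.null(dataset$spec))
    jsonlite::write_json(unclass(dataset$spec),
                         file.path(dir, "spec.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(mp)
}

#' Read an image batch from a CSV manifest
#'
#' Expects columns `path,label[,clean_label,split,fold]`; image paths are
#' resolved relative to the manifest's directory. Images must be grayscale
#' PNG; order is preserved.
#'
#' @param manifest manifest CSV path.
#' @return a `dw_dataset` (no nodule masks).
#' @export
read_image_manifest <- function(manifest) {
  if (is.null(manifest) || !file.exists(manifest))
    stop(sprintf("manifest not found: %s", manifest), call. = FALSE)
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(man)))
    stop("manifest needs columns path,label", call. = FALSE)
  if (nrow(man) == 0L) stop("empty manifest", call. = FALSE)
  base <- dirname(manifest)
  imgs <- NULL
  for (i in seq_len(nrow(man))) {
    fp <- file.path(base, man$path[i])
    if (!file.exists(fp))
      stop(sprintf("image not found: %s", fp), call. = FALSE)
    im <- png::readPNG(fp)
    if (length(dim(im)) == 3L) {
      if (dim(im)[3L] > 2L &&
          (max(abs(im[, , 1L] - im[, , 2L])) > 0 ||
           max(abs(im[, , 1L] - im[, , 3L])) > 0))
        stop(sprintf("non-grayscale image: %s", fp), call. = FALSE)
      im <- im[, , 1L]
    }
    if (is.null(imgs))
      imgs <- array(0, dim = c(nrow(im), ncol(im), nrow(man)))
    imgs[, , i] <- im
  }
  structure(list(images = imgs, labels = as.integer(man$label),
                 clean_labels = if ("clean_label" %in% names(man))
                   as.integer(man$clean_label) else NULL,
                 split = if ("split" %in% names(man)) man$split else NULL,
                 fold = if ("fold" %in% names(man)) man$fold else NULL,
                 metadata = NULL, spec = NULL),
            class = "dw_dataset")
}

# ---- pipeline stages ----------------------------------------------------

#' Pipeline stages
#'
#' Each stage reads the nested configuration, runs the corresponding part
#' of the pipeline, and writes its outputs plus a config echo and a
#' timestamped log into `out`. `run_simulate` writes the synthetic
#' dataset; `run_train` trains and saves `model.rds` + the training log;
#' `run_predict` writes per-sample MC-mean predictions; `run_uq` writes
#' the per-sample uncertainty CSV and a JSON summary; `run_gradcam`
#' writes MC Grad-CAM PNGs for a few test images; `run_evaluate`
#' evaluates the trained model on the test split; `run_crossval` runs the
#' stratified k-fold harness.
#'
#' @param cfg configuration list from [load_run_config()].
#' @param out output directory.
#' @param model_path optional trained-model RDS (defaults to
#'   `file.path(out, "model.rds")`).
#' @param n_maps number of Grad-CAM maps to write.
#' @return stage-specific value, invisibly (see each stage's outputs).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(cfg, out) {
  echo_run(cfg, out)
  ds <- cfg_dataset(cfg)
  mp <- write_dataset(ds, out)
  log_line(out, sprintf("simulated %d images -> %s",
                        dim(ds$images)[3L], mp))
  invisible(ds)
}

#' @rdname pipeline
#' @export
run_train <- function(cfg, out) {
  echo_run(cfg, out)
  ds <- cfg_dataset(cfg)
  model <- build_baresnet(cfg_model(cfg), seed = cfg$seed)
  model <- train_baresnet(model, ds, cfg_train(cfg))
  save_model(model, file.path(out, "model.rds"))
  utils::write.csv(model$training_log,
                   file.path(out, "training_log.csv"), row.names = FALSE)
  log_line(out, sprintf("trained: best val acc %.4f (epoch %d)",
                        max(model$training_log$val_acc), model$best_epoch))
  invisible(model)
}

stage_model <- function(cfg, out, model_path) {
  if (is.null(model_path)) model_path <- file.path(out, "model.rds")
  if (!file.exists(model_path)) {
    model <- build_baresnet(cfg_model(cfg), seed = cfg$seed)
  } else {
    model <- load_model(model_path)
  }
  model
}

test_subset <- function(ds) {
  if (is.null(ds$split)) ds else dataset_subset(ds, which(ds$split == "test"))
}

#' @rdname pipeline
#' @export
run_uq <- function(cfg, out, model_path = NULL) {
  echo_run(cfg, out)
  ds <- test_subset(cfg_dataset(cfg))
  model <- stage_model(cfg, out, model_path)
  mc <- mc_predict(model, ds$images, T = cfg$uq$mc_samples,
                   seed = cfg$seed)
  rep <- decompose_uncertainty(mc)
  write_uncertainty_csv(rep, file.path(out, "uncertainty.csv"))
  pred <- max.col(rep$predictive_mean) - 1L
  summary <- list(
    n = length(pred), mc_samples = cfg$uq$mc_samples,
    mean_predictive_entropy = mean(rep$predictive_entropy),
    mean_aleatoric = mean(rep$aleatoric),
    mean_epistemic = mean(rep$epistemic),
    mean_epistemic_bc = mean(rep$epistemic_bias_corrected),
    per_class = lapply(split(seq_along(pred), pred), function(i)
      list(n = length(i), mean_entropy = mean(rep$predictive_entropy[i]),
           mean_epistemic = mean(rep$epistemic[i]))))
  jsonlite::write_json(summary, file.path(out, "uq_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(out, sprintf("uq on %d samples, T=%d", length(pred),
                        cfg$uq$mc_samples))
  invisible(rep)
}

#' @rdname pipeline
#' @export
run_predict <- function(cfg, out, model_path = NULL) {
  echo_run(cfg, out)
  ds <- test_subset(cfg_dataset(cfg))
  model <- stage_model(cfg, out, model_path)
  pm <- predictive_mean(mc_predict(model, ds$images,
                                   T = cfg$uq$mc_samples, seed = cfg$seed))
  df <- data.frame(sample_id = seq_len(nrow(pm)),
                   pred_class = max.col(pm) - 1L, ph = ph_values(pm))
  utils::write.csv(cbind(df, prob = pm), file.path(out, "predictions.csv"),
                   row.names = FALSE)
  log_line(out, sprintf("predicted %d samples", nrow(pm)))
  invisible(df)
}

#' @rdname pipeline
#' @export
run_gradcam <- function(cfg, out, model_path = NULL, n_maps = 4) {
  echo_run(cfg, out)
  ds <- test_subset(cfg_dataset(cfg))
  model <- stage_model(cfg, out, model_path)
  n <- min(n_maps, dim(ds$images)[3L])
  for (i in seq_len(n)) {
    map <- mc_gradcam(model, ds$images[, , i], T = cfg$uq$mc_samples,
                      seed = cfg$seed + i)
    write_gradcam_png(map, file.path(out, sprintf("gradcam_%03d.png", i)),
                      image = ds$images[, , i])
  }
  log_line(out, sprintf("wrote %d gradcam maps", n))
  invisible(n)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(cfg, out, model_path = NULL) {
  echo_run(cfg, out)
  ds <- test_subset(cfg_dataset(cfg))
  model <- stage_model(cfg, out, model_path)
  mc <- mc_predict(model, ds$images, T = cfg$uq$mc_samples,
                   seed = cfg$seed)
  rep <- decompose_uncertainty(mc)
  pred <- max.col(rep$predictive_mean) - 1L
  metrics <- confusion_metrics(confusion_counts(pred, ds$labels))
  roc <- roc_auc(rep$predictive_mean[, 2L], ds$labels)
  ua <- uncertainty_accuracy_analysis(
    rep$predictive_mean,
    if (identical(cfg$eval$mode, "ph")) rep$ph_value else
      rep$predictive_entropy,
    ds$labels, cfg$eval$thresholds, mode = cfg$eval$mode)
  jsonlite::write_json(
    list(metrics = as.list(metrics), auc = roc$auc,
         uncertainty_accuracy = ua, mode = cfg$eval$mode),
    file.path(out, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(roc$roc_points, file.path(out, "roc_points.csv"),
                   row.names = FALSE)
  log_line(out, sprintf("evaluated %d samples: acc %.2f%%, AUC %.4f",
                        length(pred), metrics[["accuracy"]], roc$auc))
  invisible(list(metrics = metrics, auc = roc$auc,
                 uncertainty_accuracy = ua))
}

#' @rdname pipeline
#' @export
run_crossval <- function(cfg, out) {
  echo_run(cfg, out)
  ds <- cfg_dataset(cfg)
  ds$split <- NULL                              # folds replace the split
  factory <- function(train_ds, seed) {
    m <- build_baresnet(cfg_model(cfg), seed = seed)
    tc <- cfg_train(cfg); tc$seed <- seed
    train_baresnet(m, train_ds, tc)
  }
  rep <- kfold_evaluate(factory, ds, k = cfg$eval$k, seed = cfg$seed,
                        T = cfg$uq$mc_samples)
  write_eval_report(rep, out)
  log_line(out, sprintf("crossval k=%d: mean acc %.2f%%, AUC %.4f",
                        cfg$eval$k, rep$aggregate[["accuracy"]], rep$auc))
  invisible(rep)
}

# ---- command line -------------------------------------------------------

#' Command-line entry point
#'
#' `dropweakuq <subcommand> [--config PATH] [--seed INT] [--out DIR]
#' [--mc-samples INT] [--model PATH]` with subcommands `simulate`,
#' `train`, `predict`, `uq`, `gradcam`, `evaluate`, `crossval`. Flags
#' override the config file. Returns 0 on success, nonzero on error (the
#' error class is printed to stderr). The installed script lives at
#' `system.file("cli", "dropweakuq", package = "dropweakuq")`.
#'
#' @param argv character vector of arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code.
#' @export
cli_main <- function(argv) {
  sub <- c("simulate", "train", "predict", "uq", "gradcam", "evaluate",
           "crossval")
  usage <- paste0("usage: dropweakuq <", paste(sub, collapse = "|"),
                  "> [--config PATH] [--seed INT] [--out DIR] ",
                  "[--mc-samples INT] [--model PATH]")
  tryCatch({
    if (length(argv) < 1L || !argv[1L] %in% sub) stop(usage, call. = FALSE)
    cmd <- argv[1L]
    opts <- parse_flags(argv[-1L],
                        c("config", "seed", "out", "mc-samples", "model"))
    cfg <- load_run_config(opts$config)
    if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
    if (!is.null(opts[["mc-samples"]]))
      cfg$uq$mc_samples <- as.integer(opts[["mc-samples"]])
    out <- if (is.null(opts$out)) file.path("runs", cmd) else opts$out
    switch(cmd,
           simulate = run_simulate(cfg, out),
           train = run_train(cfg, out),
           predict = run_predict(cfg, out, opts$model),
           uq = run_uq(cfg, out, opts$model),
           gradcam = run_gradcam(cfg, out, opts$model),
           evaluate = run_evaluate(cfg, out, opts$model),
           crossval = run_crossval(cfg, out))
    0L
  }, error = function(e) {
    message(sprintf("error [%s]: %s", class(e)[1L], conditionMessage(e)))
    1L
  })
}

parse_flags <- function(args, known) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument: %s", a), call. = FALSE)
    key <- substring(a, 3L)
    if (!key %in% known)
      stop(sprintf("unknown flag: --%s", key), call. = FALSE)
    if (i == length(args))
      stop(sprintf("flag --%s needs a value", key), call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
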