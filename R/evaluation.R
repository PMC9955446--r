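#' Confusion counts for binary classification
#'
#' The malignant class (label 1) is the positive class by convention.
#'
#' @param pred predicted 0/1 labels.
#' @param truth true 0/1 labels.
#' @param positive the positive-class label (default 1).
#' @return an object of class `confusion_counts` (tp, fp, tn, fn).
#' @export
confusion_counts <- function(pred, truth, positive = 1L) {
  stopifnot(length(pred) == length(truth))
  p <- pred == positive; t <- truth == positive
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t),
                 positive = positive),
            class = "confusion_counts")
}

#' Standard confusion-matrix metrics (percent)
#'
#' Sensitivity = tp/(tp+fn), precision = tp/(tp+fp), accuracy =
#' (tp+tn)/total, specificity = tn/(tn+fp), F1 = harmonic mean of
#' precision and sensitivity; all scaled to percent. A zero-denominator
#' ratio is reported as `NA`, never 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return named numeric vector
#'   (sensitivity, precision, accuracy, specificity, f1).
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- rat(counts$tp, counts$tp + counts$fn)
  prec <- rat(counts$tp, counts$tp + counts$fp)
  acc <- rat(counts$tp + counts$tn,
             counts$tp + counts$fp + counts$tn + counts$fn)
  spec <- rat(counts$tn, counts$tn + counts$fp)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  100 * c(sensitivity = sens, precision = prec, accuracy = acc,
          specificity = spec, f1 = f1)
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique scores (descending); tied scores enter
#' simultaneously. AUC by the trapezoidal rule over the resulting
#' (FPR, TPR) points, which equals the probability that a random positive
#' outscores a random negative, counting ties as 1/2.
#'
#' @param scores real-valued scores (higher = more positive).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return list with `roc_points` (data frame `threshold, fpr, tpr`) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("both classes must be present", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(u) sum(scores == u & labels == 1L), 0))
  fp <- cumsum(vapply(thr, function(u) sum(scores == u & labels == 0L), 0))
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  list(roc_points = pts, auc = auc)
}

round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Aggregate per-fold metric rows
#'
#' Column-wise arithmetic mean with half-up rounding to 2 decimals
#' (matching conventional report formatting); raw means are returned in
#' the `"raw"` attribute.
#'
#' @param rows data frame or matrix of numeric metric rows (one per fold).
#' @return named numeric aggregate row, rounded to 2 decimals.
#' @export
aggregate_folds <- function(rows) {
  if (is.data.frame(rows)) {
    rows <- rows[vapply(rows, is.numeric, TRUE)]
    rows <- as.matrix(rows)
  }
  if (!is.matrix(rows) || nrow(rows) < 1L)
    stop("rows must be a nonempty matrix/data frame of metric rows",
         call. = FALSE)
  raw <- colMeans(rows)
  out <- round_half_up(raw, 2)
  attr(out, "raw") <- raw
  out
}

#' Stratified k-fold assignment
#'
#' @param labels class labels.
#' @param k number of folds (\eqn{\ge 2}).
#' @param seed integer seed.
#' @return integer fold id (1..k) per sample; folds are disjoint, cover
#'   the data, and differ in size by at most 1 per class.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (any(table(labels) < k))
    stop("each class needs at least k samples for stratification",
         call. = FALSE)
  rng <- rng_stream(substream_seed(seed, "folds"))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[stream_eval(rng, sample.int(length(idx)))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Trains a fresh model per fold via `model_factory` and evaluates on the
#' held-out fold; reports per-fold confusion metrics, the aggregate
#' (arithmetic-mean, 2-decimal) row, and pooled ROC/AUC over the held-out
#' scores.
#'
#' @param model_factory `function(train_dataset, seed)` returning a
#'   fitted model.
#' @param dataset a `dw_dataset` (or list with `images`, `labels`).
#' @param k number of folds (default 9).
#' @param seed root seed (fold assignment and per-fold training seeds).
#' @param predict_fun `function(model, images)` returning an `N x C`
#'   probability matrix; defaults to the MC predictive mean with `T`
#'   passes.
#' @param T MC passes for the default `predict_fun`.
#' @return an object of class `eval_report`.
#' @export
kfold_evaluate <- function(model_factory, dataset, k = 9, seed = 1,
                           predict_fun = NULL, T = 25) {
  labels <- as.integer(dataset$labels)
  fold <- stratified_folds(labels, k, seed)
  if (is.null(predict_fun))
    predict_fun <- function(model, images)
      predictive_mean(mc_predict(model, images, T = T,
                                 seed = substream_seed(seed, "cv_predict")))
  rows <- NULL
  pooled_scores <- numeric(0); pooled_labels <- integer(0)
  for (i in seq_len(k)) {
    te <- which(fold == i)
    tr_ds <- dataset_subset(dataset, which(fold != i))
    model <- model_factory(tr_ds, substream_seed(seed, paste0("fold", i)))
    probs <- predict_fun(model, dataset$images[, , te, drop = FALSE])
    pred <- max.col(probs) - 1L
    m <- confusion_metrics(confusion_counts(pred, labels[te]))
    rows <- rbind(rows, data.frame(fold = i, t(m)))
    pooled_scores <- c(pooled_scores, probs[, 2L])
    pooled_labels <- c(pooled_labels, labels[te])
  }
  agg <- aggregate_folds(rows[, -1L])
  roc <- roc_auc(pooled_scores, pooled_labels)
  structure(list(fold_metrics = rows, aggregate = agg,
                 roc_points = roc$roc_points, auc = roc$auc,
                 fold_assignment = fold, k = k, seed = seed),
            class = "eval_report")
}

#' Uncertainty-sorted selective-prediction analysis
#'
#' For each threshold `u`, retains samples whose uncertainty is at most
#' `u` (entropy mode) or whose PH confidence is at least `u` (PH mode)
#' and reports the retained fraction and the accuracy among retained
#' samples (`NA` when nothing is retained). Default thresholds 0.3
#' and 0.5.
#'
#' @param pred_mean `N x C` predictive-mean probability matrix.
#' @param uncertainties per-sample sorting values (predictive entropy in
#'   entropy mode, PH values in PH mode).
#' @param labels true 0-based labels.
#' @param thresholds numeric thresholds.
#' @param mode `"entropy"` (default) or `"ph"`.
#' @return data frame `threshold, retained, accuracy` (accuracy in [0,1]).
#' @export
uncertainty_accuracy_analysis <- function(pred_mean, uncertainties, labels,
                                          thresholds = c(0.3, 0.5),
                                          mode = c("entropy", "ph")) {
  mode <- match.arg(mode)
  n <- nrow(pred_mean)
  stopifnot(length(uncertainties) == n, length(labels) == n)
  pred <- max.col(pred_mean) - 1L
  correct <- pred == as.integer(labels)
  do.call(rbind, lapply(thresholds, function(u) {
    keep <- if (mode == "entropy") uncertainties <= u else
      uncertainties >= u
    data.frame(threshold = u, retained = mean(keep),
               accuracy = if (any(keep)) mean(correct[keep]) else NA_real_)
  }))
}

#' Write an evaluation report to disk
#'
#' CSV of per-fold rows plus an `Average` row (2-decimal formatting; raw
#' values retained in the JSON), ROC points CSV, and a JSON summary.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- report$fold_metrics
  num <- round_half_up(as.matrix(rows[, -1L]), 2)
  tab <- data.frame(fold = c(paste0("K-fold_", rows$fold), "Average"),
                    rbind(num, as.numeric(report$aggregate)))
  names(tab) <- c("fold", colnames(num))
  utils::write.csv(tab, file.path(dir, "fold_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc_points, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = as.list(report$aggregate),
         aggregate_raw = as.list(attr(report$aggregate, "raw")),
         auc = report$auc, k = report$k, seed = report$seed),
    file.path(dir, "eval_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d folds, AUC %.4f\n", x$k, x$auc))
  print(x$fold_metrics, row.names = FALSE)
  cat("Average:", paste(sprintf("%s=%.2f", names(x$aggregate),
                                x$aggregate), collapse = " "), "\n")
  invisible(x)
}
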