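#' Monte-Carlo stochastic prediction
#'
#' Runs `T` stochastic forward passes (fresh DropWeak / dropout masks per
#' pass, one weight-configuration draw shared across the batch) and collects
#' the per-pass class-probability vectors. The MC sample counts studied for
#' this kind of classifier are 10, 25 and 50; 25 is the package default.
#'
#' @param model a `baresnet`.
#' @param batch image batch (`H x W x N` or `H x W x 1 x N`).
#' @param T number of stochastic passes (\eqn{\ge 1}).
#' @param seed integer seed; pass `t` consumes draws from a substream
#'   derived from it, so results are reproducible.
#' @return an object of class `mc_predictive_set`: `probs` is a
#'   `T x N x C` array, with `n_samples` and per-pass seed records.
#' @export
mc_predict <- function(model, batch, T = 25, seed = 1) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be >= 1", call. = FALSE)
  x <- as_image_batch(batch)
  n <- dim(x)[4L]
  C <- model$config$n_classes
  rng <- rng_stream(substream_seed(seed, "mc_masks"))
  probs <- array(NA_real_, dim = c(T, n, C))
  seeds <- vector("list", T)
  for (t in seq_len(T)) {
    seeds[[t]] <- list(pass = t, draws_before = rng$draws)
    probs[t, , ] <- baresnet_forward(model, x, stochastic = TRUE, rng = rng)
  }
  new_mc_set(probs, seeds = seeds)
}

#' Construct an MC predictive set from raw per-pass probabilities
#'
#' @param probs `T x N x C` array; every `(t, n)` row must lie on the
#'   probability simplex (within 1e-6).
#' @param seeds optional per-pass RNG provenance records.
#' @return an object of class `mc_predictive_set`.
#' @export
new_mc_set <- function(probs, seeds = NULL) {
  d <- dim(probs)
  if (length(d) != 3L) stop("probs must be a T x N x C array", call. = FALSE)
  if (d[1L] < 1L) stop("T must be >= 1", call. = FALSE)
  sums <- apply(probs, c(1L, 2L), sum)
  if (any(abs(sums - 1) > 1e-6) || any(probs < -1e-9))
    stop("per-pass rows must lie on the probability simplex", call. = FALSE)
  structure(list(probs = probs, n_samples = d[1L], seeds = seeds),
            class = "mc_predictive_set")
}

#' Predictive mean over MC passes
#'
#' @param mc an `mc_predictive_set`.
#' @return `N x C` matrix; rows remain on the simplex.
#' @export
predictive_mean <- function(mc) {
  stopifnot(inherits(mc, "mc_predictive_set"))
  apply(mc$probs, c(2L, 3L), mean)
}

#' Shannon entropy of a categorical distribution (nats)
#'
#' Uses the convention \eqn{0 \log 0 = 0}.
#'
#' @param p probability vector on the simplex, or a matrix of row vectors.
#' @return entropy in nats (vector for matrix input), in \eqn{[0, \ln C]}.
#' @export
entropy_nats <- function(p) {
  if (is.matrix(p)) return(apply(p, 1L, entropy_nats))
  if (any(p < -1e-9) || abs(sum(p) - 1) > 1e-6)
    stop("p must lie on the probability simplex", call. = FALSE)
  p <- pmax(p, 0)
  -sum(ifelse(p > 0, p * log(p), 0))
}

# row-wise entropy without simplex re-checking (internal fast path)
row_entropy <- function(m) {
  x <- ifelse(m > 0, m * log(m), 0)
  -rowSums(x)
}

#' Decompose predictive uncertainty into aleatoric and epistemic parts
#'
#' Per sample: predictive entropy \eqn{H} of the MC-averaged distribution;
#' aleatoric = mean over passes of the per-pass entropies (expected
#' entropy); epistemic = mutual information between prediction and weight
#' configuration, computed as predictive entropy minus aleatoric. The MI is
#' nonnegative by Jensen's inequality; tiny negative floating-point
#' residue is clipped at 0 with the raw value retained.
#'
#' @param mc an `mc_predictive_set` (T = 1 is allowed; the epistemic term
#'   is then 0 by construction).
#' @param bits if `TRUE`, report in bits instead of nats.
#' @return an object of class `uncertainty_report`: per-sample
#'   `predictive_entropy`, `aleatoric`, `epistemic`, `epistemic_raw`,
#'   `epistemic_bias_corrected` (when \eqn{T \ge 3}), `predictive_mean`
#'   and `ph_value`.
#' @export
decompose_uncertainty <- function(mc, bits = FALSE) {
  stopifnot(inherits(mc, "mc_predictive_set"))
  Tn <- mc$n_samples
  pm <- predictive_mean(mc)
  H <- row_entropy(pm)
  per_pass <- apply(mc$probs, 1L, function(sl) row_entropy(
    matrix(sl, ncol = dim(mc$probs)[3L])))
  per_pass <- matrix(per_pass, ncol = Tn)       # N x T
  A <- rowMeans(per_pass)
  mi_raw <- H - A
  mi <- pmax(mi_raw, 0)
  bc <- if (Tn >= 3L) bias_corrected_mi(mc) else rep(NA_real_, nrow(pm))
  sc <- if (bits) 1 / log(2) else 1
  structure(list(predictive_entropy = H * sc, aleatoric = A * sc,
                 epistemic = mi * sc, epistemic_raw = mi_raw * sc,
                 epistemic_bias_corrected = bc * sc,
                 predictive_mean = pm, ph_value = ph_values(pm),
                 n_samples = Tn, units = if (bits) "bits" else "nats"),
            class = "uncertainty_report")
}

#' Jackknife bias-corrected mutual information
#'
#' The plug-in entropy of an MC average is biased at finite `T`. The
#' leave-one-out (jackknife) correction replaces a statistic
#' \eqn{\hat\theta} computed on all `T` passes by
#' \eqn{T\,\hat\theta - (T-1)\,\overline{\hat\theta_{(-j)}}}, where
#' \eqn{\hat\theta_{(-j)}} is computed on the `T - 1` passes excluding pass
#' `j`. The correction is applied to the predictive-entropy term and to the
#' aleatoric term (the latter is linear in the passes, so it is left
#' unchanged by the jackknife, as expected); corrected MI is their
#' difference.
#'
#' @param mc an `mc_predictive_set` with \eqn{T \ge 3}.
#' @return per-sample corrected MI (nats).
#' @export
bias_corrected_mi <- function(mc) {
  stopifnot(inherits(mc, "mc_predictive_set"))
  Tn <- mc$n_samples
  if (Tn < 3L) stop("bias correction needs T >= 3", call. = FALSE)
  d <- dim(mc$probs)
  pm <- predictive_mean(mc)                     # N x C
  H_full <- row_entropy(pm)
  per_pass <- matrix(apply(mc$probs, 1L, function(sl) row_entropy(
    matrix(sl, ncol = d[3L]))), ncol = Tn)      # N x T
  A_full <- rowMeans(per_pass)
  H_loo <- matrix(NA_real_, nrow = d[2L], ncol = Tn)
  A_loo <- matrix(NA_real_, nrow = d[2L], ncol = Tn)
  for (j in seq_len(Tn)) {
    pm_j <- (pm * Tn - mc$probs[j, , , drop = TRUE]) / (Tn - 1)
    if (is.null(dim(pm_j))) pm_j <- matrix(pm_j, nrow = d[2L])
    H_loo[, j] <- row_entropy(pmax(pm_j, 0))
    A_loo[, j] <- (A_full * Tn - per_pass[, j]) / (Tn - 1)
  }
  H_bc <- Tn * H_full - (Tn - 1) * rowMeans(H_loo)
  A_bc <- Tn * A_full - (Tn - 1) * rowMeans(A_loo)
  H_bc - A_bc
}

#' Jackknife bias-corrected entropy of an empirical distribution
#'
#' Standalone estimator used to demonstrate the bias reduction: given
#' counts or probabilities of `T` categorical draws, returns the corrected
#' plug-in entropy \eqn{T \hat H - (T-1) \overline{\hat H_{(-j)}}}.
#'
#' @param passes `T x C` matrix of per-pass (e.g. one-hot) probability
#'   rows.
#' @return corrected entropy of the column mean (nats).
#' @export
jackknife_entropy <- function(passes) {
  Tn <- nrow(passes)
  if (Tn < 3L) stop("jackknife needs T >= 3", call. = FALSE)
  pm <- colMeans(passes)
  H_full <- entropy_nats(pm / sum(pm))
  H_loo <- vapply(seq_len(Tn), function(j) {
    p <- (pm * Tn - passes[j, ]) / (Tn - 1)
    entropy_nats(pmax(p, 0) / sum(pmax(p, 0)))
  }, 0)
  Tn * H_full - (Tn - 1) * mean(H_loo)
}

#' PH ("probability of hit") confidence values
#'
#' The per-sample maximum of the predictive-mean row; used to sort and
#' threshold predictions for selective classification.
#'
#' @param pred_mean `N x C` probability matrix (rows on the simplex).
#' @return vector in \eqn{[1/C, 1]}.
#' @export
ph_values <- function(pred_mean) {
  if (is.null(dim(pred_mean))) pred_mean <- matrix(pred_mean, nrow = 1L)
  apply(pred_mean, 1L, max)
}

#' Write an uncertainty report to CSV
#'
#' Columns: `sample_id, pred_class, ph, pred_entropy, aleatoric, epistemic,
#' epistemic_bc`.
#'
#' @param report an `uncertainty_report`.
#' @param path output CSV path.
#' @param sample_ids optional identifiers (default 1..N).
#' @return the data frame written, invisibly.
#' @export
write_uncertainty_csv <- function(report, path, sample_ids = NULL) {
  stopifnot(inherits(report, "uncertainty_report"))
  n <- nrow(report$predictive_mean)
  df <- data.frame(
    sample_id = if (is.null(sample_ids)) seq_len(n) else sample_ids,
    pred_class = max.col(report$predictive_mean) - 1L,
    ph = report$ph_value,
    pred_entropy = report$predictive_entropy,
    aleatoric = report$aleatoric,
    epistemic = report$epistemic,
    epistemic_bc = report$epistemic_bias_corrected)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.uncertainty_report <- function(x, ...) {
  cat(sprintf(
    "<uncertainty_report> %d samples, T = %d (%s)\n  mean H = %.4f, aleatoric = %.4f, epistemic = %.4f\n",
    nrow(x$predictive_mean), x$n_samples, x$units,
    mean(x$predictive_entropy), mean(x$aleatoric), mean(x$epistemic)))
  invisible(x)
}
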