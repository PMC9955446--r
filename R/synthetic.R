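#' Specification of a synthetic CT phantom dataset
#'
#' Generates CT-like grayscale patches containing a single pulmonary-nodule
#' analog: benign nodules are small discs with a nearly smooth boundary,
#' malignant nodules are larger discs deformed by low-order radial
#' harmonics (a spiculation analog). Nodules are embedded in a correlated
#' Gaussian background texture with a radial vignette, plus independent
#' pixel noise. Nodule diameters follow the 3-30 mm clinical range at a
#' 1 mm = 1 px desk-scale mapping: benign diameters sample the lower part
#' of the range, malignant the upper. Aleatoric uncertainty is injected by
#' label noise (flips with `label_noise_rate`, clean labels retained) and
#' pixel noise; epistemic probes use covariate shift via
#' [generate_ood()].
#'
#' @param n_images number of images.
#' @param image_size side length in pixels (default 64).
#' @param benign_diameter,malignant_diameter diameter ranges in px.
#' @param benign_irregularity,malignant_irregularity radial-harmonic
#'   boundary amplitude (fraction of the radius).
#' @param background_sd SD of the correlated background texture.
#' @param vignette radial vignette strength (0 = flat illumination).
#' @param pixel_noise_sd SD of i.i.d. additive pixel noise.
#' @param nodule_contrast added intensity of the nodule.
#' @param label_noise_rate label-flip probability in \eqn{[0, 0.5)}.
#' @param class_balance malignant fraction in \eqn{(0, 1)}.
#' @param seed integer seed; the dataset is fully determined by it.
#' @param ood_shift optional default [ood_shift()] attached to the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_images = 2000, image_size = 64,
                           benign_diameter = c(4, 12),
                           malignant_diameter = c(12, 28),
                           benign_irregularity = 0.05,
                           malignant_irregularity = 0.35,
                           background_sd = 0.08, vignette = 0.25,
                           pixel_noise_sd = 0.02, nodule_contrast = 0.45,
                           label_noise_rate = 0.05, class_balance = 0.5,
                           seed = 1, ood_shift = NULL) {
  if (label_noise_rate < 0 || label_noise_rate >= 0.5)
    stop("label_noise_rate must lie in [0, 0.5)", call. = FALSE)
  if (class_balance <= 0 || class_balance >= 1)
    stop("class_balance must lie in (0, 1)", call. = FALSE)
  for (d in list(benign_diameter, malignant_diameter)) {
    if (any(d <= 0) || any(d >= image_size))
      stop("nodule diameters must be positive and fit in the image",
           call. = FALSE)
  }
  structure(list(n_images = as.integer(n_images),
                 image_size = as.integer(image_size),
                 benign_diameter = benign_diameter,
                 malignant_diameter = malignant_diameter,
                 benign_irregularity = benign_irregularity,
                 malignant_irregularity = malignant_irregularity,
                 background_sd = background_sd, vignette = vignette,
                 pixel_noise_sd = pixel_noise_sd,
                 nodule_contrast = nodule_contrast,
                 label_noise_rate = label_noise_rate,
                 class_balance = class_balance, seed = as.integer(seed),
                 ood_shift = ood_shift),
            class = "synthetic_spec")
}

#' Covariate-shift parameters for out-of-distribution generation
#'
#' @param texture_sd_mult multiplier on the background texture SD.
#' @param vignette_mult multiplier on the vignette strength (negative
#'   inverts it).
#' @param intensity_offset additive global intensity offset.
#' @return an object of class `ood_shift`.
#' @export
ood_shift <- function(texture_sd_mult = 2, vignette_mult = -1,
                      intensity_offset = 0) {
  structure(list(texture_sd_mult = texture_sd_mult,
                 vignette_mult = vignette_mult,
                 intensity_offset = intensity_offset),
            class = "ood_shift")
}

# FFT low-pass of white noise -> unit-SD correlated field
smooth_field <- function(noise, kern_fft) {
  f <- Re(stats::fft(stats::fft(noise) * kern_fft, inverse = TRUE)) /
    length(noise)
  s <- sd(f)
  if (s < 1e-12) f * 0 else (f - mean(f)) / s
}

gauss_kernel_fft <- function(s, sigma = 3) {
  d <- pmin(0:(s - 1), s - (0:(s - 1)))          # circular distance
  g <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  stats::fft(g / sum(g))
}

#' Generate a synthetic phantom dataset
#'
#' Fully determined by `spec$seed` (via a named substream): the same spec
#' generates bit-identical datasets.
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `dw_dataset`: `images` (`S x S x N` in
#'   \eqn{[0,1]}), `labels` (0 benign / 1 malignant, after label noise),
#'   `clean_labels`, `masks` (`S x S x N` logical nodule ground truth),
#'   `metadata` data frame (diameter, irregularity, centre, flipped), and
#'   the echoed `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  S <- spec$image_size
  n <- spec$n_images
  rng <- rng_stream(substream_seed(spec$seed, "synth"))
  kf <- gauss_kernel_fft(S)
  yy <- matrix(seq_len(S), S, S)
  xx <- matrix(rep(seq_len(S), each = S), S, S)
  ctr <- (S + 1) / 2
  rmax <- sqrt(2) * (S - 1) / 2
  vgn_r2 <- ((yy - ctr)^2 + (xx - ctr)^2) / rmax^2

  images <- array(0, dim = c(S, S, n))
  masks <- array(FALSE, dim = c(S, S, n))
  clean <- integer(n)
  meta <- data.frame(diameter = numeric(n), irregularity = numeric(n),
                     cx = numeric(n), cy = numeric(n))

  for (i in seq_len(n)) {
    draws <- stream_eval(rng, list(
      lab = runif(1), dia = runif(1), amp = runif(4), phs = runif(4),
      cen = runif(2), tex = rnorm(S * S), pix = rnorm(S * S)))
    lab <- as.integer(draws$lab < spec$class_balance)
    rng_d <- if (lab == 1L) spec$malignant_diameter else spec$benign_diameter
    dia <- rng_d[1L] + draws$dia * (rng_d[2L] - rng_d[1L])
    irr <- if (lab == 1L) spec$malignant_irregularity else
      spec$benign_irregularity
    r0 <- dia / 2
    margin <- r0 * (1 + irr) + 2
    if (2 * margin >= S) {                       # large nodule: centre it
      cy <- ctr; cx <- ctr
    } else {
      cy <- margin + draws$cen[1L] * (S - 2 * margin)
      cx <- margin + draws$cen[2L] * (S - 2 * margin)
    }
    # boundary radius as a low-order harmonic deformation of the disc
    amp <- irr * (0.4 + 0.6 * draws$amp) / seq(1, 2.5, length.out = 4L)
    phs <- 2 * pi * draws$phs
    dy <- yy - cy; dx <- xx - cx
    rr <- sqrt(dy^2 + dx^2)
    th <- atan2(dx, dy)
    rb <- r0
    for (k in 1:4) rb <- rb + r0 * amp[k] * cos((k + 1) * th + phs[k])
    edge <- pmin(pmax((rb - rr) / 1.5 + 0.5, 0), 1)
    bump <- edge^2 * (3 - 2 * edge)              # smoothstep profile
    tex <- smooth_field(matrix(draws$tex, S, S), kf) * spec$background_sd
    img <- 0.40 * (1 - spec$vignette * vgn_r2) + tex +
      spec$nodule_contrast * bump +
      spec$pixel_noise_sd * matrix(draws$pix, S, S)
    images[, , i] <- pmin(pmax(img, 0), 1)
    masks[, , i] <- rr <= rb
    clean[i] <- lab
    meta$diameter[i] <- dia; meta$irregularity[i] <- irr
    meta$cx[i] <- cx; meta$cy[i] <- cy
  }
  flip <- stream_eval(rng, runif(n)) < spec$label_noise_rate
  labels <- ifelse(flip, 1L - clean, clean)
  meta$flipped <- flip
  structure(list(images = images, labels = as.integer(labels),
                 clean_labels = clean, masks = masks, metadata = meta,
                 spec = spec),
            class = "dw_dataset")
}

#' Generate an out-of-distribution (covariate-shifted) dataset
#'
#' Same nodule and label process as [generate_dataset()] (same seed, same
#' draws) with shifted background statistics; a zero shift reproduces the
#' base dataset bit-identically, and labels are untouched so the class
#' balance is preserved.
#'
#' @param spec a [synthetic_spec()].
#' @param shift an [ood_shift()]; defaults to `spec$ood_shift` or
#'   `ood_shift()`.
#' @return a `dw_dataset`.
#' @export
generate_ood <- function(spec, shift = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(shift)) shift <- spec$ood_shift
  if (is.null(shift)) shift <- ood_shift()
  stopifnot(inherits(shift, "ood_shift"))
  sp <- spec
  sp$background_sd <- spec$background_sd * shift$texture_sd_mult
  sp$vignette <- spec$vignette * shift$vignette_mult
  ds <- generate_dataset(sp)
  if (shift$intensity_offset != 0)
    ds$images <- pmin(pmax(ds$images + shift$intensity_offset, 0), 1)
  ds$spec <- spec; ds$ood_shift <- shift
  ds
}

#' @export
print.dw_dataset <- function(x, ...) {
  cat(sprintf("<dw_dataset> %d images %dx%d, %.1f%% malignant, %d flipped labels\n",
              dim(x$images)[3L], dim(x$images)[1L], dim(x$images)[2L],
              100 * mean(x$clean_labels == 1L), sum(x$metadata$flipped)))
  invisible(x)
}

#' Subset a dataset by index
#' @param dataset a `dw_dataset`.
#' @param idx integer indices.
#' @return a `dw_dataset` with the selected samples (split retained).
#' @export
dataset_subset <- function(dataset, idx) {
  out <- dataset
  out$images <- dataset$images[, , idx, drop = FALSE]
  out$labels <- dataset$labels[idx]
  out$clean_labels <- dataset$clean_labels[idx]
  if (!is.null(dataset$masks))
    out$masks <- dataset$masks[, , idx, drop = FALSE]
  if (!is.null(dataset$metadata))
    out$metadata <- dataset$metadata[idx, , drop = FALSE]
  if (!is.null(dataset$split)) out$split <- dataset$split[idx]
  out
}
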