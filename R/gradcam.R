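#' Grad-CAM class-attention map
#'
#' Standard Grad-CAM from a chosen convolutional stage: channel weights are
#' the spatial averages of the gradient of the pre-SoftMax score of
#' `target_class` with respect to the stage's (post-ReLU) activation maps;
#' the map is the ReLU of the gradient-weighted channel sum, bilinearly
#' upsampled to the input size and max-normalized to \eqn{[0,1]} (a raw map
#' that is identically \eqn{\le 0} yields an all-zero heat map).
#'
#' @param model a `baresnet`.
#' @param image a single grayscale image (`H x W`).
#' @param target_class 0-based class index; default = the predicted class.
#' @param layer `"block2"` (default: last convolutional stage),
#'   `"block1"`, or `"conv1"`.
#' @return an object of class `gradcam_map`: `heat` (`H x W` in
#'   \eqn{[0,1]}), `raw` (layer-resolution pre-normalization map),
#'   `target_class`, `source_layer`, `n_mc`.
#' @export
gradcam <- function(model, image, target_class = NULL, layer = "block2") {
  gradcam_impl(model, image, target_class, layer, stochastic = FALSE,
               rng = NULL)
}

#' Monte-Carlo averaged Grad-CAM
#'
#' Averages `T` per-pass (pre-normalization) Grad-CAM maps under fresh
#' DropWeak / dropout masks, then upsamples and normalizes. Averaging
#' before normalization preserves the relative magnitudes across passes.
#'
#' @inheritParams gradcam
#' @param T number of stochastic passes (\eqn{\ge 1}).
#' @param seed integer seed for the mask substream.
#' @return a `gradcam_map` with `n_mc = T`.
#' @export
mc_gradcam <- function(model, image, target_class = NULL, layer = "block2",
                       T = 25, seed = 1) {
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be >= 1", call. = FALSE)
  rng <- rng_stream(substream_seed(seed, "gradcam_masks"))
  acc <- NULL; tc <- target_class
  for (t in seq_len(T)) {
    m <- gradcam_impl(model, image, tc, layer, stochastic = TRUE, rng = rng)
    if (is.null(tc)) tc <- m$target_class  # fix the class across passes
    acc <- if (is.null(acc)) m$raw else acc + m$raw
  }
  finish_gradcam(acc / T, dim(as_image_batch(image))[1:2], tc, layer, T)
}

gradcam_layers <- c(block2 = "a5", block1 = "a2", conv1 = "a0")

gradcam_impl <- function(model, image, target_class, layer, stochastic,
                         rng) {
  stopifnot(inherits(model, "baresnet"))
  if (!layer %in% names(gradcam_layers))
    stop(sprintf("layer must be one of %s (a convolutional stage)",
                 paste(names(gradcam_layers), collapse = ", ")),
         call. = FALSE)
  x <- as_image_batch(image)
  if (dim(x)[4L] != 1L) stop("gradcam expects a single image", call. = FALSE)
  fw <- baresnet_forward_full(model, x, stochastic = stochastic, rng = rng,
                              want_cache = TRUE)
  C <- model$config$n_classes
  if (is.null(target_class)) target_class <- which.max(fw$probs[1L, ]) - 1L
  if (target_class < 0L || target_class >= C)
    stop("target_class out of range", call. = FALSE)
  dlogits <- matrix(0, nrow = 1L, ncol = C)
  dlogits[1L, target_class + 1L] <- 1           # pre-SoftMax score gradient
  bw <- baresnet_backward(model, fw$cache, dlogits)
  A <- fw$cache[[gradcam_layers[[layer]]]]      # h x w x k x 1
  dA <- bw$dact[[layer]]
  k <- dim(A)[3L]
  alpha <- vapply(seq_len(k), function(ki) mean(dA[, , ki, 1L]), 0)
  raw <- matrix(0, nrow = dim(A)[1L], ncol = dim(A)[2L])
  for (ki in seq_len(k)) raw <- raw + alpha[ki] * A[, , ki, 1L]
  raw <- relu(raw)
  finish_gradcam(raw, dim(x)[1:2], target_class, layer, 1L)
}

finish_gradcam <- function(raw, size, target_class, layer, n_mc) {
  heat <- upsample_bilinear(raw, size[1L], size[2L])
  mx <- max(heat)
  heat <- if (mx > 0) heat / mx else heat * 0
  structure(list(heat = heat, raw = raw,
                 target_class = as.integer(target_class),
                 source_layer = layer, n_mc = as.integer(n_mc)),
            class = "gradcam_map")
}

# centre-aligned bilinear upsampling with edge clamping
upsample_bilinear <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  sy <- (seq_len(H) - 0.5) * h / H - 0.5
  sx <- (seq_len(W) - 0.5) * w / W - 0.5
  y0 <- pmin(pmax(floor(sy), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(sx), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- pmin(pmax(sy - y0, 0), 1); fx <- pmin(pmax(sx - x0, 0), 1)
  m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x1 + 1, drop = FALSE]
  m10 <- m[y1 + 1, x0 + 1, drop = FALSE]; m11 <- m[y1 + 1, x1 + 1, drop = FALSE]
  Fy <- matrix(fy, H, W); Fx <- matrix(fx, H, W, byrow = TRUE)
  m00 * (1 - Fy) * (1 - Fx) + m01 * (1 - Fy) * Fx +
    m10 * Fy * (1 - Fx) + m11 * Fy * Fx
}

#' Write a Grad-CAM map as 8-bit grayscale PNG
#'
#' Optionally also writes an overlay PNG (heat blended over the input
#' image) and always writes a JSON sidecar with class, layer and MC count.
#'
#' @param map a `gradcam_map`.
#' @param path output PNG path (sidecar written next to it).
#' @param image optional original image for an `_overlay.png`.
#' @return `path`, invisibly.
#' @export
write_gradcam_png <- function(map, path, image = NULL) {
  stopifnot(inherits(map, "gradcam_map"))
  png::writePNG(map$heat, path)
  if (!is.null(image)) {
    img <- as_image_batch(image)[, , 1L, 1L]
    over <- pmin(pmax(0.5 * img + 0.5 * map$heat, 0), 1)
    png::writePNG(over, sub("\\.png$", "_overlay.png", path))
  }
  jsonlite::write_json(
    list(target_class = map$target_class, source_layer = map$source_layer,
         n_mc = map$n_mc),
    sub("\\.png$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf("<gradcam_map> %dx%d heat, class %d, layer %s, T = %d\n",
              nrow(x$heat), ncol(x$heat), x$target_class, x$source_layer,
              x$n_mc))
  invisible(x)
}
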