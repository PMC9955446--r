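#' Architecture configuration for the mini residual classifier
#'
#' A compact two-block residual convolutional network for grayscale patches.
#' Topology: stem conv (3x3) + maxpool; residual block 1 (two 3x3 convs,
#' identity shortcut) whose convolutions are wrapped in DropWeak masking;
#' transition conv + maxpool; residual block 2 regularized only by plain
#' node dropout on its pooled features; global average pooling; a fully
#' connected layer whose weights also receive DropWeak masking; SoftMax.
#'
#' @param input_size `c(H, W)` in pixels; both divisible by 8 (default 64).
#' @param channels two per-stage channel counts `c(C1, C2)`.
#' @param n_classes number of classes (\eqn{\ge 2}).
#' @param dropweak a [dropweak_spec()] applied to block-1 convolutions and
#'   the fully connected weights.
#' @param dropout_prob plain dropout probability after block 2.
#' @param nb_head logical; reserve an optional Gaussian naive-Bayes fusion
#'   head (see [naive_bayes_head_fit()]).
#' @return an object of class `baresnet_config`.
#' @export
baresnet_config <- function(input_size = c(64, 64), channels = c(8, 16),
                            n_classes = 2, dropweak = dropweak_spec(),
                            dropout_prob = 0.1, nb_head = FALSE) {
  input_size <- as.integer(input_size)
  if (length(input_size) == 1L) input_size <- rep(input_size, 2L)
  if (any(input_size < 16L) || any(input_size %% 8L != 0L))
    stop("input_size must be >= 16 and divisible by 8", call. = FALSE)
  channels <- as.integer(channels)
  if (length(channels) != 2L || any(channels < 1L))
    stop("channels must be two positive counts", call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  check_prob(dropout_prob, "dropout_prob")
  stopifnot(inherits(dropweak, "dropweak_spec"))
  structure(list(input_size = input_size, channels = channels,
                 n_classes = as.integer(n_classes), dropweak = dropweak,
                 dropout_prob = dropout_prob, nb_head = isTRUE(nb_head)),
            class = "baresnet_config")
}

#' Training configuration
#'
#' Defaults are desk-scale; the full-scale reference settings (Adam at
#' 1e-5, batch 16, 750 epochs, 256x256 inputs, 80/10/10 split) remain
#' selectable and are recorded in the training log when used.
#'
#' @param learning_rate Adam step size (> 0).
#' @param lr_factor multiplier applied on a validation-accuracy plateau.
#' @param patience epochs without validation improvement before decay.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed root seed; all training randomness derives from it.
#' @param split train/validation/test fractions (positive, sum to 1).
#' @param augmentation logical; horizontal flip + small rotation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, lr_factor = 0.2,
                         patience = 10, batch_size = 16, epochs = 20,
                         seed = 42, split = c(0.8, 0.1, 0.1),
                         augmentation = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (length(split) != 3L || any(split <= 0) ||
      abs(sum(split) - 1) > 1e-8)
    stop("split must be 3 positive fractions summing to 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, lr_factor = lr_factor,
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 split = split, augmentation = isTRUE(augmentation)),
            class = "train_config")
}

he_init <- function(shape, rng) {
  fan_in <- if (length(shape) == 4L) prod(shape[1:3]) else shape[2L]
  array(stream_eval(rng, rnorm(prod(shape))) * sqrt(2 / fan_in), dim = shape)
}

#' Build an untrained model
#'
#' He-normal initialization from a named substream of `seed`.
#'
#' @param cfg a [baresnet_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `baresnet` (weights, config, training log).
#' @export
build_baresnet <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "baresnet_config"))
  rng <- rng_stream(substream_seed(seed, "init"))
  C1 <- cfg$channels[1L]; C2 <- cfg$channels[2L]; C <- cfg$n_classes
  w <- list(
    conv1 = list(w = he_init(c(3, 3, 1, C1), rng), b = numeric(C1)),
    b1a   = list(w = he_init(c(3, 3, C1, C1), rng), b = numeric(C1)),
    b1b   = list(w = he_init(c(3, 3, C1, C1), rng), b = numeric(C1)),
    trans = list(w = he_init(c(3, 3, C1, C2), rng), b = numeric(C2)),
    b2a   = list(w = he_init(c(3, 3, C2, C2), rng), b = numeric(C2)),
    b2b   = list(w = he_init(c(3, 3, C2, C2), rng), b = numeric(C2)),
    fc    = list(w = he_init(c(C, C2), rng), b = numeric(C)))
  structure(list(weights = w, config = cfg, norm = NULL,
                 training_log = NULL, nb_head = NULL,
                 init_seed = as.integer(seed)),
            class = "baresnet")
}

#' Number of trainable parameters
#' @param model a `baresnet`.
#' @return integer count.
#' @export
param_count <- function(model) {
  sum(vapply(model$weights, function(l) length(l$w) + length(l$b), 0))
}

# ---- low-level layer helpers -------------------------------------------

conv_fwd_r <- function(x, w, b) {
  d <- dim(w)
  conv2d_fwd(x, dim(x), matrix(w, prod(d[1:3]), d[4L]), b,
             d[1L], d[2L], (d[1L] - 1L) %/% 2L, 1L)
}

conv_bwd_r <- function(x, w, dy, need_dx = TRUE) {
  d <- dim(w)
  r <- conv2d_bwd(x, dim(x), matrix(w, prod(d[1:3]), d[4L]), dy,
                  d[1L], d[2L], (d[1L] - 1L) %/% 2L, 1L, need_dx)
  r$dw <- array(r$dw, dim = d)
  r
}

relu <- function(x) { x[x < 0] <- 0; x }

gap_fwd <- function(a) {
  d <- dim(a)
  hw <- d[1L] * d[2L]
  matrix(colSums(matrix(a, nrow = hw)), nrow = d[3L], ncol = d[4L]) / hw
}

gap_bwd <- function(dg, d) {
  hw <- d[1L] * d[2L]
  array(rep(as.vector(dg), each = hw) / hw, dim = d)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

as_image_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("batch must be an array", call. = FALSE)
  if (length(d) == 2L) array(x, dim = c(d, 1L, 1L))
  else if (length(d) == 3L) array(x, dim = c(d[1L], d[2L], 1L, d[3L]))
  else if (length(d) == 4L) x
  else stop("batch must have 2-4 dimensions", call. = FALSE)
}

# ---- forward / backward -------------------------------------------------

# Full forward pass. `masks` may pre-supply the stochastic mask sets (used
# by the training loop to share masks across a batch's forward/backward).
# `inject` (internal, validation only): list(layer = "a0"/"a2"/"a5",
# delta = array) added to that post-ReLU activation, so finite-difference
# oracles can probe the score as a function of an intermediate activation.
baresnet_forward_full <- function(model, x, stochastic = FALSE, rng = NULL,
                                  want_cache = FALSE, masks = NULL,
                                  standardize = TRUE, inject = NULL) {
  cfg <- model$config
  x <- as_image_batch(x)
  d <- dim(x)
  if (d[1L] != cfg$input_size[1L] || d[2L] != cfg$input_size[2L] ||
      d[3L] != 1L)
    stop(sprintf("expected %dx%d grayscale input, got %dx%dx%d",
                 cfg$input_size[1L], cfg$input_size[2L],
                 d[1L], d[2L], d[3L]), call. = FALSE)
  if (standardize && !is.null(model$norm))
    x <- (x - model$norm$mean) / model$norm$sd
  w <- model$weights
  dw <- cfg$dropweak
  C2 <- cfg$channels[2L]

  if (stochastic && is.null(masks)) {
    if (is.null(rng)) stop("stochastic pass needs an rng stream",
                           call. = FALSE)
    masks <- sample_baresnet_masks(model, rng)
  }

  dwconv <- function(xin, layer, mk) {
    if (is.null(mk)) {
      conv_fwd_r(xin, w[[layer]]$w, w[[layer]]$b)
    } else {
      apply_dropweak(w[[layer]]$w, xin, mk, dw, bias = w[[layer]]$b)
    }
  }

  bump <- function(a, nm) {
    if (!is.null(inject) && identical(inject$layer, nm)) a + inject$delta
    else a
  }
  z0 <- conv_fwd_r(x, w$conv1$w, w$conv1$b); a0 <- bump(relu(z0), "a0")
  p0l <- maxpool2_fwd(a0, dim(a0)); P0 <- p0l$out
  z1 <- dwconv(P0, "b1a", masks$b1a); a1 <- relu(z1)
  z2 <- dwconv(a1, "b1b", masks$b1b)
  s1 <- z2 + P0; a2 <- bump(relu(s1), "a2")
  p1l <- maxpool2_fwd(a2, dim(a2)); P1 <- p1l$out
  z3 <- conv_fwd_r(P1, w$trans$w, w$trans$b); a3 <- relu(z3)
  p2l <- maxpool2_fwd(a3, dim(a3)); P2 <- p2l$out
  z4 <- conv_fwd_r(P2, w$b2a$w, w$b2a$b); a4 <- relu(z4)
  z5 <- conv_fwd_r(a4, w$b2b$w, w$b2b$b)
  s2 <- z5 + P2; a5 <- bump(relu(s2), "a5")
  g <- gap_fwd(a5)                              # C2 x N
  gd <- if (!is.null(masks$dropout)) g * masks$dropout else g
  fc_w <- if (!is.null(masks$fc))
    masked_weights(w$fc$w, masks$fc, dw)$effective_weights else w$fc$w
  logits <- t(fc_w %*% gd + w$fc$b)             # N x C
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (want_cache)
    out$cache <- list(x = x, z0 = z0, a0 = a0, p0 = p0l, z1 = z1, a1 = a1,
                      s1 = s1, a2 = a2, p1 = p1l, z3 = z3, a3 = a3,
                      p2 = p2l, z4 = z4, a4 = a4, s2 = s2, a5 = a5,
                      g = g, gd = gd, fc_w = fc_w, masks = masks)
  out
}

# Sample one pass's mask sets: DropWeak for b1a/b1b/fc, plain (inverted-
# scaled) dropout multiplier for the block-2 features. One draw per pass,
# shared across the batch: each pass is one weight-configuration draw.
sample_baresnet_masks <- function(model, rng) {
  cfg <- model$config
  dw <- cfg$dropweak
  fc_spec <- dw; fc_spec$node_drop_prob <- 0  # FC logits are never dropped
  mk <- list(
    b1a = sample_mask_set(model$weights$b1a$w, dw, rng),
    b1b = sample_mask_set(model$weights$b1b$w, dw, rng),
    fc  = sample_mask_set(model$weights$fc$w, fc_spec, rng))
  p <- cfg$dropout_prob
  if (p > 0) {
    keep <- sample_node_mask(cfg$channels[2L], p, rng)
    mk$dropout <- keep / (1 - p)
  }
  mk
}

# mask multiplier that maps d(effective W) -> d(master W)
mask_multiplier <- function(mk, spec) {
  if (is.null(mk)) return(1)
  masked_weights(array(1, dim = dim_or_len(mk$weight_mask)), mk,
                 spec)$effective_weights
}

node_mult <- function(mk, spec) {
  if (is.null(mk)) return(NULL)
  mk$node_mask * node_scale(spec)
}

# Backward pass from d(logits); returns weight gradients plus the gradients
# of the score wrt selected post-ReLU activations (for Grad-CAM).
baresnet_backward <- function(model, cache, dlogits) {
  w <- model$weights
  dw <- model$config$dropweak
  mk <- cache$masks
  dL <- t(dlogits)                               # C x N
  g_fc_eff <- dL %*% t(cache$gd)
  grads <- list(fc = list(w = g_fc_eff * mask_multiplier(mk$fc, dw),
                          b = rowSums(dL)))
  dgd <- t(cache$fc_w) %*% dL                    # C2 x N
  dg <- if (!is.null(mk$dropout)) dgd * mk$dropout else dgd
  da5 <- gap_bwd(dg, dim(cache$a5))
  ds2 <- da5 * (cache$s2 > 0)
  r <- conv_bwd_r(cache$a4, w$b2b$w, ds2)
  grads$b2b <- list(w = r$dw, b = r$db)
  dz4 <- r$dx * (cache$z4 > 0)
  r <- conv_bwd_r(cache$p2$out, w$b2a$w, dz4)
  grads$b2a <- list(w = r$dw, b = r$db)
  dP2 <- r$dx + ds2                              # residual shortcut
  da3 <- maxpool2_bwd(dP2, cache$p2$idx, dim(cache$a3))
  dz3 <- da3 * (cache$z3 > 0)
  r <- conv_bwd_r(cache$p1$out, w$trans$w, dz3)
  grads$trans <- list(w = r$dw, b = r$db)
  da2 <- maxpool2_bwd(r$dx, cache$p1$idx, dim(cache$a2))
  ds1 <- da2 * (cache$s1 > 0)
  nm_b1b <- node_mult(mk$b1b, dw)
  dz2 <- if (is.null(nm_b1b)) ds1 else sweep_channels(ds1, nm_b1b)
  w_b1b_eff <- w$b1b$w * mask_multiplier(mk$b1b, dw)
  r <- conv_bwd_r(cache$a1, w_b1b_eff, dz2)
  grads$b1b <- list(w = r$dw * mask_multiplier(mk$b1b, dw), b = r$db)
  da1 <- r$dx * (cache$z1 > 0)
  nm_b1a <- node_mult(mk$b1a, dw)
  dz1 <- if (is.null(nm_b1a)) da1 else sweep_channels(da1, nm_b1a)
  w_b1a_eff <- w$b1a$w * mask_multiplier(mk$b1a, dw)
  r <- conv_bwd_r(cache$p0$out, w_b1a_eff, dz1)
  grads$b1a <- list(w = r$dw * mask_multiplier(mk$b1a, dw), b = r$db)
  dP0 <- r$dx + ds1
  da0 <- maxpool2_bwd(dP0, cache$p0$idx, dim(cache$a0))
  dz0 <- da0 * (cache$z0 > 0)
  r <- conv_bwd_r(cache$x, w$conv1$w, dz0, need_dx = FALSE)
  grads$conv1 <- list(w = r$dw, b = r$db)
  list(grads = grads,
       dact = list(block2 = da5, block1 = da2, conv1 = da0))
}

#' Forward pass: class probabilities for a batch
#'
#' @param model a trained or untrained `baresnet`.
#' @param batch grayscale images: `H x W`, `H x W x N`, or `H x W x 1 x N`,
#'   values in \eqn{[0,1]}; standardized internally with the statistics of
#'   the model's training split when the model has been trained.
#' @param stochastic if `TRUE`, fresh DropWeak / dropout masks are sampled
#'   from `rng`; if `FALSE` (default) all masks are disabled and the pass is
#'   deterministic.
#' @param rng an [rng_stream()]; required when `stochastic = TRUE`.
#' @return `N x C` matrix of SoftMax probabilities (rows sum to 1).
#' @export
baresnet_forward <- function(model, batch, stochastic = FALSE, rng = NULL) {
  stopifnot(inherits(model, "baresnet"))
  # chunk large batches to bound activation memory
  x <- as_image_batch(batch)
  n <- dim(x)[4L]
  chunk <- 256L
  if (n <= chunk)
    return(baresnet_forward_full(model, x, stochastic, rng)$probs)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  do.call(rbind, lapply(idx, function(i)
    baresnet_forward_full(model, x[, , , i, drop = FALSE],
                          stochastic, rng)$probs))
}

# ---- training -----------------------------------------------------------

adam_state <- function(weights) {
  lapply(weights, function(l) list(
    mw = array(0, dim = dim_or_len(l$w)), vw = array(0, dim = dim_or_len(l$w)),
    mb = numeric(length(l$b)), vb = numeric(length(l$b))))
}

adam_step <- function(weights, grads, st, lr, t, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (nm in names(weights)) {
    s <- st[[nm]]; g <- grads[[nm]]
    s$mw <- b1 * s$mw + (1 - b1) * g$w
    s$vw <- b2 * s$vw + (1 - b2) * g$w^2
    s$mb <- b1 * s$mb + (1 - b1) * g$b
    s$vb <- b2 * s$vb + (1 - b2) * g$b^2
    weights[[nm]]$w <- weights[[nm]]$w - lr * (s$mw / c1) /
      (sqrt(s$vw / c2) + eps)
    weights[[nm]]$b <- weights[[nm]]$b - lr * (s$mb / c1) /
      (sqrt(s$vb / c2) + eps)
    st[[nm]] <- s
  }
  list(weights = weights, state = st)
}

onehot <- function(labels, C) {
  m <- matrix(0, nrow = length(labels), ncol = C)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Assign stratified train/validation/test splits
#'
#' @param labels integer class labels.
#' @param split three positive fractions summing to 1.
#' @param seed integer seed.
#' @return character vector of `"train"`, `"val"`, `"test"`.
#' @export
make_split <- function(labels, split = c(0.8, 0.1, 0.1), seed = 42) {
  rng <- rng_stream(substream_seed(seed, "split"))
  out <- character(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[stream_eval(rng, sample.int(length(idx)))]
    n <- length(idx)
    n_tr <- round(split[1L] * n)
    n_va <- round(split[2L] * n)
    out[idx[seq_len(n_tr)]] <- "train"
    out[idx[n_tr + seq_len(min(n_va, n - n_tr))]] <- "val"
    out[idx[seq_len(n) > n_tr + n_va]] <- "test"
  }
  out
}

augment_batch <- function(x, rng) {
  # horizontal flip w.p. 0.5 + rotation in [-10, 10] degrees per image
  d <- dim(x)
  u <- stream_eval(rng, runif(2L * d[4L]))
  for (n in seq_len(d[4L])) {
    img <- x[, , 1L, n]
    if (u[2L * n - 1L] < 0.5) img <- img[, rev(seq_len(d[2L]))]
    ang <- (u[2L * n] * 2 - 1) * 10
    x[, , 1L, n] <- rotate_nn(img, ang)
  }
  x
}

# nearest-neighbour rotation about the image centre, edge padding by
# clamping source coordinates
rotate_nn <- function(img, degrees) {
  h <- nrow(img); w <- ncol(img)
  th <- degrees * pi / 180
  ct <- cos(th); st <- sin(th)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(rep(seq_len(w), each = h), h, w) - cx
  sy <- pmin(pmax(round(ct * yy - st * xx + cy), 1), h)
  sx <- pmin(pmax(round(st * yy + ct * xx + cx), 1), w)
  matrix(img[cbind(as.vector(sy), as.vector(sx))], h, w)
}

#' Train the model
#'
#' Minimizes cross-entropy with fresh DropWeak masks per training batch,
#' evaluates validation accuracy (deterministic pass) after every epoch,
#' decays the learning rate by `lr_factor` on a validation plateau, and
#' returns the best-validation checkpoint. A non-finite loss aborts with a
#' `dropweakuq_divergence` error carrying the last good checkpoint in
#' `condition$model`.
#'
#' @param model a `baresnet` from [build_baresnet()].
#' @param dataset a `dw_dataset` (see [generate_dataset()]) or a list with
#'   `images` (`H x W x N` in \eqn{[0,1]}) and `labels` (0-based integers);
#'   an optional `split` element with values train/val/test is honoured.
#' @param tcfg a [train_config()].
#' @return the trained `baresnet` (best validation checkpoint) with
#'   `training_log` (epoch, train_loss, val_acc, lr) and the
#'   standardization statistics of its training split.
#' @export
train_baresnet <- function(model, dataset, tcfg = train_config()) {
  stopifnot(inherits(model, "baresnet"), inherits(tcfg, "train_config"))
  cfg <- model$config
  imgs <- as_image_batch(dataset$images)
  labels <- as.integer(dataset$labels)
  n <- dim(imgs)[4L]
  if (n < 2L || length(labels) != n) stop("empty or inconsistent dataset",
                                          call. = FALSE)
  split <- dataset$split
  if (is.null(split)) split <- make_split(labels, tcfg$split, tcfg$seed)
  tr <- which(split == "train"); va <- which(split == "val")
  if (length(tr) == 0L || length(va) == 0L)
    stop("empty train or validation split", call. = FALSE)

  # standardization from the training split only (no leakage)
  mu <- mean(imgs[, , , tr])
  sg <- sd(imgs[, , , tr]); if (sg < 1e-8) sg <- 1
  model$norm <- list(mean = mu, sd = sg)

  rng_masks <- rng_stream(substream_seed(tcfg$seed, "masks"))
  rng_batch <- rng_stream(substream_seed(tcfg$seed, "batches"))
  rng_aug <- rng_stream(substream_seed(tcfg$seed, "augment"))
  st <- adam_state(model$weights)
  lr <- tcfg$learning_rate
  best <- list(acc = -Inf, weights = model$weights, epoch = 0L)
  since_improve <- 0L
  log <- NULL
  tglob <- 0L
  C <- cfg$n_classes
  va_x <- imgs[, , , va, drop = FALSE]
  va_y <- labels[va]

  for (ep in seq_len(tcfg$epochs)) {
    ord <- tr[stream_eval(rng_batch, sample.int(length(tr)))]
    batches <- split(ord, ceiling(seq_along(ord) / tcfg$batch_size))
    ep_loss <- 0; ep_n <- 0L
    for (b in batches) {
      xb <- imgs[, , , b, drop = FALSE]
      if (tcfg$augmentation) xb <- augment_batch(xb, rng_aug)
      mk <- sample_baresnet_masks(model, rng_masks)
      fw <- baresnet_forward_full(model, xb, stochastic = TRUE,
                                  masks = mk, want_cache = TRUE)
      yb <- labels[b]
      p_true <- fw$probs[cbind(seq_along(b), yb + 1L)]
      loss <- -mean(log(pmax(p_true, 1e-12)))
      if (!is.finite(loss)) {
        model$weights <- best$weights
        model$training_log <- log
        cond <- structure(class = c("dropweakuq_divergence", "error",
                                    "condition"),
                          list(message = "non-finite training loss",
                               call = sys.call(), model = model))
        stop(cond)
      }
      ep_loss <- ep_loss + loss * length(b); ep_n <- ep_n + length(b)
      dlogits <- (fw$probs - onehot(yb, C)) / length(b)
      bw <- baresnet_backward(model, fw$cache, dlogits)
      tglob <- tglob + 1L
      upd <- adam_step(model$weights, bw$grads, st, lr, tglob)
      model$weights <- upd$weights; st <- upd$state
    }
    val_pred <- max.col(baresnet_forward(model, va_x)) - 1L
    val_acc <- mean(val_pred == va_y)
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                 val_acc = val_acc, lr = lr))
    if (val_acc > best$acc + 1e-12) {
      best <- list(acc = val_acc, weights = model$weights, epoch = ep)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= tcfg$patience) {
        lr <- lr * tcfg$lr_factor
        since_improve <- 0L
      }
    }
  }
  model$weights <- best$weights
  model$training_log <- log
  model$best_epoch <- best$epoch
  model$train_seed <- tcfg$seed
  model$split <- split
  model
}

#' Save / load a model checkpoint
#'
#' Round-tripping reproduces bit-identical weights.
#'
#' @param model a `baresnet`.
#' @param path file path.
#' @return `load_model` returns the `baresnet`; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "baresnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "baresnet"))
  m
}

#' @export
print.baresnet <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<baresnet> %dx%d input, channels %s, %d classes, %d params%s\n",
              cfg$input_size[1L], cfg$input_size[2L],
              paste(cfg$channels, collapse = "/"), cfg$n_classes,
              param_count(x),
              if (is.null(x$training_log)) " (untrained)" else
                sprintf(", best val acc %.3f",
                        max(x$training_log$val_acc))))
  invisible(x)
}

#' Fit the optional Gaussian naive-Bayes fusion head
#'
#' Fits a Gaussian naive-Bayes model (via \pkg{e1071}) on the
#' global-average-pooled penultimate features of the training split; the
#' fused prediction is the renormalized elementwise product of the SoftMax
#' and naive-Bayes posteriors. Off by default (`nb_head` in
#' [baresnet_config()]); provided as one defensible reading of a
#' ResNet/naive-Bayes fusion, since no canonical recipe exists.
#'
#' @param model a trained `baresnet`.
#' @param dataset the dataset the model was trained on.
#' @param var_floor variance floor for degenerate per-class features.
#' @return the model with a fitted `nb_head` (class means/SDs/priors).
#' @export
naive_bayes_head_fit <- function(model, dataset, var_floor = 1e-6) {
  stopifnot(inherits(model, "baresnet"))
  split <- if (!is.null(model$split)) model$split else dataset$split
  idx <- if (is.null(split)) seq_along(dataset$labels) else
    which(split == "train")
  feats <- penultimate_features(model, dataset$images[, , idx, drop = FALSE])
  y <- as.integer(dataset$labels[idx])
  classes <- sort(unique(y))
  head <- list(classes = classes, var_floor = var_floor,
               prior = vapply(classes, function(cl) mean(y == cl), 0),
               mean = t(vapply(classes, function(cl)
                 colMeans(feats[y == cl, , drop = FALSE]),
                 numeric(ncol(feats)))),
               sd = t(vapply(classes, function(cl)
                 pmax(apply(feats[y == cl, , drop = FALSE], 2L, sd),
                      sqrt(var_floor)), numeric(ncol(feats)))))
  model$nb_head <- head
  model
}

# penultimate (GAP) features, deterministic pass
penultimate_features <- function(model, batch) {
  x <- as_image_batch(batch)
  n <- dim(x)[4L]
  idx <- split(seq_len(n), ceiling(seq_len(n) / 256L))
  do.call(rbind, lapply(idx, function(i) {
    fw <- baresnet_forward_full(model, x[, , , i, drop = FALSE],
                                want_cache = TRUE)
    t(fw$cache$g)
  }))
}

#' Fused SoftMax x naive-Bayes prediction
#'
#' @param model a `baresnet` with a fitted head
#'   (see [naive_bayes_head_fit()]).
#' @param batch image batch.
#' @return `N x C` matrix of fused probabilities (rows sum to 1).
#' @export
nb_fused_predict <- function(model, batch) {
  if (is.null(model$nb_head)) stop("no fitted naive-Bayes head",
                                   call. = FALSE)
  head <- model$nb_head
  probs <- baresnet_forward(model, batch)
  nb_post <- nb_posterior(head, penultimate_features(model, batch))
  fused <- probs * nb_post
  fused / rowSums(fused)
}

# Gaussian naive-Bayes class posterior from pooled features
nb_posterior <- function(head, feats) {
  loglik <- vapply(seq_along(head$classes), function(k) {
    rowSums(dnorm(feats, rep(head$mean[k, ], each = nrow(feats)),
                  rep(head$sd[k, ], each = nrow(feats)), log = TRUE)) +
      log(head$prior[k])
  }, numeric(nrow(feats)))
  if (is.null(dim(loglik))) loglik <- matrix(loglik, nrow = 1L)
  loglik <- loglik - apply(loglik, 1L, max)
  exp(loglik) / rowSums(exp(loglik))
}
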