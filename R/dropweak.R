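#' @useDynLib dropweakuq, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm quantile sd setNames dnorm median
NULL

#' Weak-weight rules
#'
#' A weak rule decides which low-magnitude weights are zeroed on every
#' stochastic pass. `weak_absolute(tau)` zeroes entries with `|w| < tau`
#' (strict, so `tau = 0` keeps everything). `weak_quantile(q)` zeroes the
#' `floor(q * n)` entries of smallest magnitude, with ties broken by
#' ascending flat index so the mask is a deterministic function of the
#' weights.
#'
#' @param tau nonnegative magnitude threshold.
#' @param q quantile in \eqn{[0, 1]}.
#' @return an object of class `weak_rule`.
#' @export
weak_absolute <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("tau must be a single finite number >= 0", call. = FALSE)
  structure(list(type = "absolute", value = tau), class = "weak_rule")
}

#' @rdname weak_absolute
#' @export
weak_quantile <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0 || q > 1)
    stop("q must lie in [0, 1]", call. = FALSE)
  structure(list(type = "quantile", value = q), class = "weak_rule")
}

#' DropWeak mask hyperparameters
#'
#' DropWeak combines three masking mechanisms in a single stochastic pass:
#' node dropout (whole output units / channels, Bernoulli with probability
#' `node_drop_prob`), DropConnect-style per-weight dropping (Bernoulli with
#' probability `weight_drop_prob`, scalar or a per-weight array), and
#' deterministic zeroing of low-magnitude ("weak") weights under
#' `weak_rule`. Masks are applied as per-pass views over the intact master
#' weights, so dropped entries rejoin automatically on the next pass.
#'
#' With `scale_mode = "inverted"` the surviving Bernoulli-masked weights are
#' rescaled by \eqn{1/(1-\rho)} and kept nodes by \eqn{1/(1-p)}, so the
#' masked pass is unbiased for the dense pass; the weak mask is never
#' rescale-compensated. `scale_mode = "none"` disables compensation (useful
#' for exact reduction checks against plain dropout / DropConnect).
#'
#' @param node_drop_prob probability in \eqn{[0,1]} of dropping an output
#'   unit (conv: an output channel).
#' @param weight_drop_prob probability in \eqn{[0,1]} of dropping each
#'   weight; a scalar or an array of the weight tensor's shape.
#' @param weak_rule a [weak_absolute()] or [weak_quantile()] rule.
#' @param scale_mode `"inverted"` (default) or `"none"`.
#' @return an object of class `dropweak_spec`.
#' @export
dropweak_spec <- function(node_drop_prob = 0.1, weight_drop_prob = 0.1,
                          weak_rule = weak_quantile(0.10),
                          scale_mode = c("inverted", "none")) {
  scale_mode <- match.arg(scale_mode)
  check_prob(node_drop_prob, "node_drop_prob", scalar = TRUE)
  check_prob(weight_drop_prob, "weight_drop_prob", scalar = FALSE)
  if (!inherits(weak_rule, "weak_rule"))
    stop("weak_rule must be created by weak_absolute() or weak_quantile()",
         call. = FALSE)
  structure(list(node_drop_prob = node_drop_prob,
                 weight_drop_prob = weight_drop_prob,
                 weak_rule = weak_rule, scale_mode = scale_mode),
            class = "dropweak_spec")
}

check_prob <- function(p, what, scalar = TRUE) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  if (scalar && length(p) != 1L)
    stop(sprintf("%s must be a single probability", what), call. = FALSE)
  invisible(TRUE)
}

#' Sample a Bernoulli weight (DropConnect) mask
#'
#' Each entry is 0 (dropped) with probability `rho` and 1 otherwise,
#' independently; `rho` may be a scalar or an array matching `shape`.
#'
#' @param shape integer vector of tensor dimensions.
#' @param rho drop probability (scalar or array of product(shape) entries).
#' @param rng an [rng_stream()].
#' @return binary array with dimensions `shape`.
#' @export
sample_weight_mask <- function(shape, rho, rng) {
  shape <- as.integer(shape)
  if (length(shape) < 1L || any(shape < 1L))
    stop("shape must be a nonempty positive dimension vector", call. = FALSE)
  n <- prod(shape)
  check_prob(rho, "rho", scalar = FALSE)
  if (length(rho) != 1L && length(rho) != n)
    stop("rho array does not match shape", call. = FALSE)
  u <- stream_eval(rng, runif(n))
  m <- as.numeric(u >= rho)
  if (length(shape) > 1L) dim(m) <- shape
  m
}

#' Sample a Bernoulli node (dropout) mask
#'
#' @param n_units number of output units.
#' @param p_node drop probability in \eqn{[0,1]}.
#' @param rng an [rng_stream()].
#' @return binary keep-indicator vector of length `n_units`.
#' @export
sample_node_mask <- function(n_units, p_node, rng) {
  check_prob(p_node, "p_node", scalar = TRUE)
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 1L)
  u <- stream_eval(rng, runif(n_units))
  as.numeric(u >= p_node)
}

#' Deterministic weak-weight mask
#'
#' Zeroes low-magnitude weights per the rule; purely a function of the
#' weights (no randomness), hence idempotent.
#'
#' @param weights numeric array of weights (must be finite).
#' @param weak_rule a [weak_absolute()] or [weak_quantile()] rule.
#' @return binary array of the weights' shape (1 = keep).
#' @export
weak_weight_mask <- function(weights, weak_rule) {
  if (!all(is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  if (!inherits(weak_rule, "weak_rule"))
    stop("weak_rule must be a weak_rule object", call. = FALSE)
  w <- as.vector(weights)
  m <- rep(1, length(w))
  if (weak_rule$type == "absolute") {
    m[abs(w) < weak_rule$value] <- 0
  } else {
    k <- floor(weak_rule$value * length(w))
    if (k > 0) {
      ord <- order(abs(w), seq_along(w))  # ties: ascending flat index
      m[ord[seq_len(k)]] <- 0
    }
  }
  if (!is.null(dim(weights))) dim(m) <- dim(weights)
  m
}

#' Sample a full DropWeak mask set for one stochastic pass
#'
#' @param weights weight tensor (matrix `out x in`, or conv array
#'   `kh x kw x Cin x Cout`).
#' @param spec a [dropweak_spec()].
#' @param rng an [rng_stream()].
#' @return an object of class `mask_set` with `node_mask`, `weight_mask`,
#'   `weak_mask` and `seed_state`.
#' @export
sample_mask_set <- function(weights, spec, rng) {
  stopifnot(inherits(spec, "dropweak_spec"))
  n_units <- n_output_units(weights)
  wm <- sample_weight_mask(dim_or_len(weights), spec$weight_drop_prob, rng)
  nm <- sample_node_mask(n_units, spec$node_drop_prob, rng)
  structure(list(node_mask = nm, weight_mask = wm,
                 weak_mask = weak_weight_mask(weights, spec$weak_rule),
                 seed_state = list(seed = rng$seed, draws = rng$draws)),
            class = "mask_set")
}

dim_or_len <- function(x) if (is.null(dim(x))) length(x) else dim(x)

n_output_units <- function(weights) {
  d <- dim(weights)
  if (is.null(d)) length(weights)
  else if (length(d) == 2L) d[1L]       # affine: rows are output units
  else if (length(d) == 4L) d[4L]       # conv: output channels
  else stop("weights must be a matrix or a 4-d conv array", call. = FALSE)
}

# Effective per-pass weights: W * bernoulli * weak, with optional inverted
# rescaling of the Bernoulli-surviving entries. Never mutates `weights`.
masked_weights <- function(weights, masks, spec) {
  mult <- masks$weight_mask * masks$weak_mask
  if (spec$scale_mode == "inverted") {
    rho <- spec$weight_drop_prob
    mult <- mult * ifelse(rho < 1, 1 / (1 - rho), 0)
  }
  eff <- weights * mult
  structure(list(effective_weights = eff, base_weights_untouched = TRUE),
            class = "masked_weight_view")
}

node_scale <- function(spec) {
  p <- spec$node_drop_prob
  if (spec$scale_mode == "inverted" && p < 1) 1 / (1 - p) else 1
}

#' Apply DropWeak-masked weights to inputs
#'
#' Computes the pre-activation of one stochastic pass:
#' the node mask (rescaled under inverted scaling) applied to the outputs of
#' `(weight_mask * weak_mask * weights)` applied to `inputs`. Supports an
#' affine map (matrix weights `out x in`, inputs `in x N`) and 2-d
#' cross-correlation (conv weights `kh x kw x Cin x Cout`, inputs
#' `H x W x Cin x N`, stride 1, "same" zero padding).
#'
#' With all masks equal to 1 and `scale_mode = "none"` the result is
#' bit-identical to the unmasked dense application.
#'
#' @param weights weight tensor.
#' @param inputs input matrix or 4-d activation array.
#' @param masks a `mask_set` sampled for these weights
#'   (see [sample_mask_set()]).
#' @param spec the [dropweak_spec()] the masks were sampled under.
#' @param bias optional bias vector (length = output units); default zeros.
#' @return pre-activation array (`out x N`, or `H x W x Cout x N`).
#' @export
apply_dropweak <- function(weights, inputs, masks, spec, bias = NULL) {
  stopifnot(inherits(masks, "mask_set"), inherits(spec, "dropweak_spec"))
  if (!identical(dim_or_len(masks$weight_mask), dim_or_len(weights)))
    stop("mask shape does not match weights", call. = FALSE)
  eff <- masked_weights(weights, masks, spec)$effective_weights
  nm <- masks$node_mask * node_scale(spec)
  d <- dim(weights)
  if (is.null(d) || length(d) == 2L) {
    wmat <- if (is.null(d)) matrix(eff, nrow = 1L) else eff
    x <- if (is.null(dim(inputs))) matrix(inputs, ncol = 1L) else inputs
    if (ncol(wmat) != nrow(x)) stop("input shape mismatch", call. = FALSE)
    b <- if (is.null(bias)) 0 else bias
    out <- wmat %*% x + b
    out * nm
  } else if (length(d) == 4L) {
    if (length(dim(inputs)) != 4L || dim(inputs)[3L] != d[3L])
      stop("input shape mismatch", call. = FALSE)
    b <- if (is.null(bias)) numeric(d[4L]) else bias
    out <- conv2d_fwd(inputs, dim(inputs),
                      matrix(eff, nrow = prod(d[1:3]), ncol = d[4L]),
                      b, d[1L], d[2L], (d[1L] - 1L) %/% 2L, 1L)
    sweep_channels(out, nm)
  } else stop("weights must be a matrix or 4-d conv array", call. = FALSE)
}

# multiply an (H, W, C, N) array by a per-channel factor
sweep_channels <- function(x, f) {
  d <- dim(x)
  x * rep(rep(f, each = d[1L] * d[2L]), times = d[4L])
}

#' Magnitude-inverse per-weight drop-probability schedule
#'
#' Optional dynamic schedule for `weight_drop_prob`: each weight's drop
#' probability is `rho_max` times the rank percentile of `-|w|`, so the
#' smallest-magnitude weight is dropped with probability close to
#' `rho_max` and the largest with probability close to 0. Ties share the
#' average rank. Intended to be recomputed per epoch and passed as the
#' `weight_drop_prob` array of a [dropweak_spec()].
#'
#' @param weights weight tensor.
#' @param rho_max maximum drop probability in \eqn{[0,1]}.
#' @return array of per-weight drop probabilities (same shape).
#' @export
rho_magnitude_schedule <- function(weights, rho_max = 0.5) {
  check_prob(rho_max, "rho_max", scalar = TRUE)
  n <- length(weights)
  r <- rank(-abs(as.vector(weights)), ties.method = "average")
  out <- rho_max * (r - 1) / max(n - 1, 1)
  if (!is.null(dim(weights))) dim(out) <- dim(weights)
  out
}

#' Monte-Carlo estimate of the expected masked activation
#'
#' Averages [apply_dropweak()] over `n_samples` independent mask
#' realizations; under inverted scaling the estimate converges to the
#' deterministic unmasked pre-activation by the law of large numbers.
#'
#' @inheritParams apply_dropweak
#' @param n_samples number of mask realizations (\eqn{\ge 1}).
#' @param rng an [rng_stream()] supplying all mask draws.
#' @return array of the pre-activation shape.
#' @export
mc_activation_estimate <- function(weights, inputs, spec, n_samples, rng,
                                   bias = NULL) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop("n_samples must be >= 1", call. = FALSE)
  acc <- NULL
  for (i in seq_len(n_samples)) {
    m <- sample_mask_set(weights, spec, rng)
    o <- apply_dropweak(weights, inputs, m, spec, bias = bias)
    acc <- if (is.null(acc)) o else acc + o
  }
  acc / n_samples
}
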