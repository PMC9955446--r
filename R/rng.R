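#' Seeded RNG substreams
#'
#' All stochastic components (mask draws, data synthesis, fold assignment,
#' minibatch shuffling) consume from named substreams derived from a single
#' root seed, so every stage of a run is independently reproducible and
#' masks drawn in one component do not perturb another.
#'
#' A stream is an environment carrying its own Mersenne-Twister state;
#' drawing from it never touches (and is never affected by) the global RNG.
#'
#' @param seed integer root seed.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(abs(seed) %% (.Machine$integer.max - 1L)))
  env$state <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  env$seed <- as.integer(abs(seed) %% (.Machine$integer.max - 1L))
  env$draws <- 0L
  class(env) <- "rng_stream"
  env
}

#' Derive a named substream seed from a root seed
#'
#' Deterministic 31-bit hash of (root seed, stream name); keeps derived
#' seeds inside R's integer range.
#'
#' @param seed integer root seed.
#' @param name character stream name (e.g. "masks", "data", "folds").
#' @return integer seed for [rng_stream()].
#' @export
substream_seed <- function(seed, name) {
  h <- as.double(as.integer(abs(seed) %% (.Machine$integer.max - 1L)))
  for (ch in utf8ToInt(as.character(name))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h)
}

#' Evaluate an expression under a stream's RNG state
#'
#' The stream's saved state is installed, `expr` is evaluated lazily, the
#' advanced state is stored back, and the global RNG is restored
#' untouched.
#'
#' @param rng an [rng_stream()].
#' @param expr expression drawing random numbers.
#' @return the value of `expr`.
#' @export
stream_eval <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  rng$draws <- rng$draws + 1L
  expr
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream> seed", x$seed, "-", x$draws, "draw calls\n")
  invisible(x)
}
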