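#' Seeded uniform random number stream
#'
#' A mutable stream of Uniform(0,1) deviates backed by R's Mersenne-Twister
#' generator, isolated from the global RNG state: drawing from a stream never
#' disturbs `.Random.seed`, and identical seeds yield identical streams.  All
#' randomness in the package flows through streams so that an entire run is
#' reproducible from one master seed.
#'
#' @param seed Integer seed.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- with_global_rng(NULL, function() {
    set.seed(e$seed, kind = "Mersenne-Twister")
    get(".Random.seed", envir = globalenv())
  })
  class(e) <- "rng_stream"
  e
}

# Run `fn` with the global .Random.seed swapped to `state` (or freshly seeded
# when NULL), restoring the caller's RNG state afterwards.
with_global_rng <- function(state, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  fn()
}

#' Draw uniform deviates from a stream
#'
#' @param rng An [rng_stream()].
#' @param n Number of deviates.
#' @return Numeric vector in (0, 1); the stream state advances by `n` draws.
#' @export
rng_uniform <- function(rng, n = 1L) {
  stopifnot(inherits(rng, "rng_stream"))
  u <- with_global_rng(rng$state, function() {
    u <- stats::runif(n)
    rng$state <- get(".Random.seed", envir = globalenv())
    u
  })
  u
}

#' Draw standard normal deviates from a stream
#'
#' Implemented as `qnorm(rng_uniform(...))` so that every deviate traces back
#' to exactly one uniform draw from the stream.
#'
#' @inheritParams rng_uniform
#' @return Numeric vector of N(0,1) deviates.
#' @export
rng_normal <- function(rng, n = 1L) {
  stats::qnorm(rng_uniform(rng, n))
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream seed=", x$seed, ">\n", sep = "")
  invisible(x)
}
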