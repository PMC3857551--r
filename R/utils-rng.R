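# Reproducibility helpers: all randomness in the package flows through
# these so that every public function is a pure function of (inputs, seed).

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `code`, and
#' restores the previous state on exit, so library calls never perturb user
#' randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a deterministic sub-stream seed
#'
#' Hashes a root seed together with integer tags (stage index, replicate
#' index, ...) into a new seed in `[1, 2^31 - 2]`.  Lehmer-style update with
#' multiplier 48271 modulo the Mersenne prime 2^31 - 1; all intermediates
#' stay below 2^53 so the double arithmetic is exact.  Adding replicates or
#' stages never perturbs the streams of earlier ones.
#'
#' @param seed root integer seed.
#' @param ... integer tags identifying the sub-stream.
#' @return An integer seed.
#' @keywords internal
substream_seed <- function(seed, ...) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% m)
  for (tag in c(...)) {
    h <- (h * 48271 + (abs(as.numeric(tag)) %% m) + 1) %% m
  }
  as.integer(max(1, h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
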