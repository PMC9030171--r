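# Named, independent RNG streams.
#
# Every stochastic purpose (patient attributes, one stream per patient's
# activity durations, booking visitors) draws from its own stream, seeded by a
# stable integer hash of (seed, keys...). Adding or removing an activity in one
# scenario therefore never perturbs draws belonging to another purpose, which
# is what makes paired-seed scenario comparisons and the cleaning-monotonicity
# property deterministic.

#' Stable integer hash of a seed and a list of keys
#'
#' Multiplicative congruential mixing modulo 2^31 - 1. Character keys are
#' folded to integers by summing their UTF-8 code points. The result is a
#' valid, portable seed for [set.seed()].
#'
#' @param seed Integer base seed.
#' @param ... Additional integer or character keys mixed into the hash.
#' @return A single integer in \[0, 2^31 - 2\].
#' @export
#' @examples
#' mix_seed(1L, 3L, "durations")
mix_seed <- function(seed, ...) {
  keys <- list(...)
  x <- as.numeric(seed) %% 2147483647
  for (k in keys) {
    if (is.character(k)) k <- sum(utf8ToInt(k))
    # 69069 * (2^31 - 2) < 2^53, so the double arithmetic below is exact
    x <- (x * 69069 + as.numeric(k)) %% 2147483647
  }
  as.integer(x)
}

# A stream is an environment holding a private .Random.seed state.
new_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  g <- globalenv()
  old <- if (exists(".Random.seed", envir = g, inherits = FALSE)) {
    get(".Random.seed", envir = g)
  }
  set.seed(as.integer(seed))
  s$state <- get(".Random.seed", envir = g)
  if (is.null(old)) {
    rm(".Random.seed", envir = g)
  } else {
    assign(".Random.seed", old, envir = g)
  }
  s
}

# Evaluate fn() with the stream's RNG state swapped in; the global RNG state
# of the caller is left untouched.
with_stream <- function(stream, fn) {
  g <- globalenv()
  old <- if (exists(".Random.seed", envir = g, inherits = FALSE)) {
    get(".Random.seed", envir = g)
  }
  assign(".Random.seed", stream$state, envir = g)
  on.exit({
    stream$state <- get(".Random.seed", envir = g)
    if (is.null(old)) {
      rm(".Random.seed", envir = g)
    } else {
      assign(".Random.seed", old, envir = g)
    }
  })
  fn()
}
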