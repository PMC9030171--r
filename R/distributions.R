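# Parametric duration laws for clinic activities.

#' Duration distribution specification
#'
#' Activity durations in the clinic model follow one of two laws, in seconds:
#' a normal law (mean `p1`, standard deviation `p2`, truncated at zero by
#' resampling negative draws) or a uniform law on \[`p1`, `p2`\].
#'
#' @param family `"normal"` or `"uniform"`.
#' @param p1 Mean (normal) or lower bound (uniform), seconds.
#' @param p2 Standard deviation (normal, must be > 0) or upper bound (uniform,
#'   must be >= `p1`). A degenerate uniform with `p1 == p2` is allowed and
#'   yields the constant `p1`.
#' @return An object of class `dist_spec`.
#' @export
#' @examples
#' dist_spec("normal", 300, 13)
#' dist_spec("uniform", 900, 1800)
dist_spec <- function(family = c("normal", "uniform"), p1, p2) {
  family <- match.arg(family)
  if (!is.numeric(p1) || !is.numeric(p2) || length(p1) != 1L || length(p2) != 1L) {
    stop("p1 and p2 must be single numbers", call. = FALSE)
  }
  if (family == "normal" && p2 <= 0) {
    stop("normal law requires a positive standard deviation p2", call. = FALSE)
  }
  if (family == "uniform" && p1 > p2) {
    stop("uniform law requires p1 <= p2", call. = FALSE)
  }
  structure(list(family = family, p1 = as.numeric(p1), p2 = as.numeric(p2)),
            class = "dist_spec")
}

#' Draw activity durations
#'
#' Samples `n` nonnegative durations from a [dist_spec()]. Normal draws are
#' truncated at zero by resampling; uniform draws lie in \[`p1`, `p2`\].
#' Draws consume the current RNG state unless a stream is supplied.
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws.
#' @param stream Optional private RNG stream (internal use); when `NULL` the
#'   session RNG is used.
#' @return Numeric vector of `n` durations in seconds.
#' @export
sample_duration <- function(spec, n = 1L, stream = NULL) {
  if (!inherits(spec, "dist_spec")) stop("spec must be a dist_spec", call. = FALSE)
  draw <- function() {
    if (spec$family == "uniform") {
      if (spec$p1 == spec$p2) rep(spec$p1, n) else stats::runif(n, spec$p1, spec$p2)
    } else {
      x <- stats::rnorm(n, spec$p1, spec$p2)
      while (any(bad <- x < 0)) {
        x[bad] <- stats::rnorm(sum(bad), spec$p1, spec$p2)
      }
      x
    }
  }
  if (is.null(stream)) draw() else with_stream(stream, draw)
}

#' @export
mean.dist_spec <- function(x, ...) {
  if (x$family == "uniform") (x$p1 + x$p2) / 2 else x$p1
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(%g, %g) s\n", x$family, x$p1, x$p2))
  invisible(x)
}
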