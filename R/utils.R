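#' @keywords internal
"_PACKAGE"

# Shared argument checks used across the package. All stop() with a message
# naming the offending argument; no partial results are ever returned.

stop_if_not_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}

stop_if_not_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

stop_if_not_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || any(is.na(x)) || (strict && any(x <= 0)) ||
      (!strict && any(x < 0))) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(as.numeric(x))
}

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on the
#' monotone decreasing trigamma function. Used when estimating the prior
#' degrees of freedom of the variance distribution by method of moments.
#'
#' @param y Positive numeric vector.
#' @return Numeric vector `x` with `trigamma(x) == y` to near machine
#'   precision; `Inf` maps to 0 and values below ~1e-6 map to `1/y`.
#' @examples
#' trigamma_inverse(trigamma(2.5))
#' @export
trigamma_inverse <- function(y) {
  stopifnot(is.numeric(y), all(y >= 0, na.rm = TRUE))
  out <- y
  for (i in seq_along(y)) {
    yi <- y[i]
    if (is.na(yi)) next
    if (yi > 1e7) { out[i] <- 1 / sqrt(yi); next }
    if (yi < 1e-6) { out[i] <- 1 / yi; next }
    x <- 0.5 + 1 / yi
    for (iter in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    out[i] <- x
  }
  out
}

# Deterministic run under a seed without disturbing the caller's RNG.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
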