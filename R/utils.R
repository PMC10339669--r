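#' Expand a global seed into independent stream seeds
#'
#' All stochastic stages (gap surrogates, field surrogates, start selection,
#' bootstraps) draw their seed from one global seed through this mixer, so a
#' single integer reproduces an entire analysis while keeping the streams
#' decoupled.
#'
#' @param seed Integer global seed.
#' @param stream Character stream label, e.g. `"gap"`, `"fields"`,
#'   `"starts"`, `"bootstrap"`.
#' @return An integer seed below 2^31 suitable for [set.seed()].
#' @examples
#' expand_seed(1L, "gap")
#' @export
expand_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  # Knuth-style multiplicative mix kept inside 31 bits via repeated modulo
  x <- (as.numeric(seed) %% 2147483647) + 1
  x <- (x * 48271) %% 2147483647
  x <- (x + h * 69621) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer(x)
}

.assert_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  invisible(x)
}

.assert_scalar <- function(x, what, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("%s must be a finite numeric scalar", what), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("%s must be positive", what), call. = FALSE)
  invisible(x)
}

# First-order (delta-method) propagation of independent standard errors
# through a function of a named numeric vector.
.delta_se <- function(fn, x, se, rel_h = 1e-6) {
  stopifnot(length(x) == length(se))
  f0 <- fn(x)
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    h <- max(abs(x[i]) * rel_h, 1e-12)
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  list(value = f0, se = sqrt(sum((g * se)^2)))
}

# Fixed-format numeric writer so identical runs give byte-identical tables.
.fmt_num <- function(x, digits = 10) {
  formatC(x, digits = digits, format = "g")
}
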