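# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
next_fast_len <- function(n) {
  # smallest 5-smooth integer >= n; keeps R's mixed-radix FFT fast
  stopifnot(n >= 1)
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Analytic signal via frequency-domain construction (one-sided spectrum).
# Works column-wise on a matrix; returns a complex matrix of the same shape.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

# Zero-phase IIR filtering of matrix columns: forward-backward application
# with odd-reflection edge padding and steady-state edge initialization
# (compiled; see src/filtfilt.cpp).
#' @keywords internal
#' @noRd
filtfilt_mat <- function(b, a, x) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, ncol = 1L)
  y <- filtfilt_cpp(as.numeric(b), as.numeric(a), x)
  if (single) drop(y) else y
}

#' @keywords internal
#' @noRd
wrap_pi <- function(x) {
  # map angles to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
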