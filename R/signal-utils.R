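#' Zero-phase band-pass filtering of a uniformly sampled trace
#'
#' Two designs are provided. `"butter"` is a 4th-order Butterworth applied
#' forward and backward (`signal::filtfilt`), the standard choice for the
#' ripple band (100-250 Hz at 2 kHz). `"fft"` is an exact zero-phase spectral
#' band-pass; it is used for the theta band (6-10 Hz), whose normalized edge
#' frequencies at a 2 kHz sampling rate are too close to DC for a stable
#' high-order IIR design.
#'
#' @param x numeric vector, uniformly sampled.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param method `"butter"` or `"fft"`.
#' @param order Butterworth order (ignored for `"fft"`).
#' @return filtered trace, same length as `x`.
#' @export
bandpass <- function(x, fs, low, high, method = c("butter", "fft"), order = 4) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), fs > 0, low > 0, low < high, high < fs / 2)
  if (method == "butter") {
    b <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    as.numeric(signal::filtfilt(b, x))
  } else {
    n <- length(x)
    f <- seq(0, n - 1) / n * fs
    f <- pmin(f, fs - f)            # two-sided frequency axis
    keep <- f >= low & f <= high
    Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
  }
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Doubles positive frequencies and zeroes negative ones, so the result's
#' modulus is the instantaneous amplitude envelope and its argument the
#' instantaneous phase of `x`.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Gaussian smoothing with edge renormalization
#'
#' Convolves with a Gaussian kernel truncated at +/-4 sigma. Near the ends of
#' the vector the kernel is renormalized over the available samples, so there
#' is no wraparound and no zero-padding bias -- appropriate for rate curves on
#' a linear (non-circular) trajectory. `NA`s are treated as missing and
#' excluded from the local normalization.
#'
#' @param x numeric vector (may contain `NA`).
#' @param sigma kernel sd in samples; `sigma = 0` returns `x` unchanged.
#' @return smoothed vector; positions where no finite value falls under the
#'   kernel stay `NA`.
#' @export
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  n <- length(x)
  ok <- is.finite(x)
  x0 <- ifelse(ok, x, 0)
  num <- stats::convolve(c(rep(0, half), x0, rep(0, half)), rev(k), type = "filter")
  den <- stats::convolve(c(rep(0, half), as.numeric(ok), rep(0, half)), rev(k), type = "filter")
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Wrap angles in degrees into [0, 360)
#' @param deg numeric vector of angles in degrees.
#' @return wrapped angles.
#' @export
wrap360 <- function(deg) deg %% 360

# Deterministic child seed from a parent seed and a stream index.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12289L) %% 2147483647)
}

# data.table non-standard evaluation is used internally (io module)
.datatable.aware <- TRUE
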