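#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn %||%
#' @importFrom stats fft rnorm runif median var sd coef pf pchisq setNames
#' @importFrom utils head tail
NULL

# Zero-phase 4th-order Butterworth band-pass. `band` in Hz, `rate` in Hz.
# Order is the order of the underlying one-pass filter; filtfilt doubles the
# effective roll-off.
butter_bandpass <- function(x, rate, band, order = 4L) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[2] >= rate / 2) {
    abort("upper band edge must be below the Nyquist frequency")
  }
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

butter_lowpass <- function(x, rate, cutoff, order = 4L) {
  if (cutoff >= rate / 2) abort("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  signal::filtfilt(bf, x)
}

# Analytic signal via the frequency-domain construction: double positive
# frequencies, zero negative ones, keep DC and (for even n) Nyquist.
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
  fft(fft(x) * h, inverse = TRUE) / n
}

# Reflective padding on both ends, for edge-safe filtering of short trials.
pad_reflect <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  c(rev(x[2:(n_pad + 1L)]), x, rev(x[(n - n_pad):(n - 1L)]))
}

unpad <- function(x, n_pad, n) x[(n_pad + 1L):(n_pad + n)]

# filtfilt on a reflect-padded copy, trimmed back to the original length.
filt_padded <- function(x, filter_fun, pad_s, rate) {
  n <- length(x)
  n_pad <- as.integer(round(pad_s * rate))
  xp <- pad_reflect(x, n_pad)
  n_pad <- min(n_pad, n - 1L)
  unpad(filter_fun(xp), n_pad, n)
}

# Canonical text label for a contrast fraction: "6.25", "12.5", "25", ...
contrast_label <- function(frac) as.character(frac * 100)

assert_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) abort(paste0(what, " contains non-finite values"))
  invisible(x)
}

vnorm <- function(v) sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
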