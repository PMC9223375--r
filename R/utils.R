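# Shared numerical helpers: seed derivation, Welch spectra, IIR filtering.

#' Derive a reproducible child seed from a root seed and a name path
#'
#' All randomness in the package flows from one root seed through named
#' child streams (per subject, trial and modality), so regenerating one
#' modality never depends on the order in which the others were drawn.
#' The hash is a plain polynomial string hash modulo 2^31 - 1, chosen for
#' portability rather than cryptographic strength.
#'
#' @param root integer root seed.
#' @param ... further character/numeric path components naming the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(42, "trial", 3, "EMG")
child_seed <- function(root, ...) {
  key <- paste(c(format(root), vapply(list(...), format, "")), collapse = "/")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a temporary RNG state seeded from `seed`.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647L), expr)
}

# Round half away from zero (reported TS quantisation; base round() is
# banker's rounding).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Welch averaged-periodogram power spectral density
#'
#' Mean of Hann-windowed, per-segment demeaned periodograms over segments
#' with 50% overlap. One-sided density in units of `x^2 / Hz`.
#'
#' @param x numeric series.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples; shortened to `length(x)` when
#'   the series is shorter than one segment.
#' @param overlap fractional overlap between consecutive segments.
#' @return A list with `freq` (Hz) and `psd` components.
#' @export
welch_psd <- function(x, fs, seg_len = length(x), overlap = 0.5) {
  n <- length(x)
  if (n < 8) stop("series too short for spectral estimation")
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  u <- sum(w^2)
  nf <- floor(seg_len / 2)
  acc <- numeric(nf + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    xf <- stats::fft(seg)[1:(nf + 1L)]
    acc <- acc + Mod(xf)^2 / (fs * u)
  }
  psd <- acc / length(starts)
  # fold negative frequencies into the one-sided estimate
  if (nf >= 2) psd[2:nf] <- 2 * psd[2:nf]
  list(freq = (0:nf) * fs / seg_len, psd = psd)
}

#' Integrated band power of a Welch spectrum
#'
#' Rectangle-rule integral of the PSD over `(lo, hi]`.
#'
#' @param sp a spectrum from [welch_psd()].
#' @param lo,hi band edges in Hz.
#' @return Power (variance) in the band.
#' @export
band_power <- function(sp, lo, hi) {
  df <- sp$freq[2] - sp$freq[1]
  sum(sp$psd[sp$freq > lo & sp$freq <= hi]) * df
}

# Single-pass IIR b/a filter with zero initial conditions, built on the
# C-level stats::filter (convolution for the numerator, recursion for the
# denominator) -- much faster than R-level loops on long traces.
iir_filter <- function(b, a, x) {
  n <- length(x)
  v <- b[1] * x
  for (j in seq_along(b)[-1]) {
    v[j:n] <- v[j:n] + b[j] * x[1:(n - j + 1)]
  }
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1] / a[1], method = "recursive"))
  }
  v / a[1]
}

# Zero-phase Butterworth filtering (forward-backward, odd-symmetric
# reflection padding to damp edge transients).
# type: "low", "high" or "pass" (band-pass with edges w = c(lo, hi) in Hz).
bw_filter <- function(x, fs, w, type = c("low", "high", "pass"), order = 4) {
  type <- match.arg(type)
  nyq <- fs / 2
  if (any(w >= nyq)) {
    stop(sprintf("filter edge %.3g Hz not below Nyquist (%.3g Hz)", max(w), nyq))
  }
  flt <- switch(type,
    low  = signal::butter(order, w / nyq, type = "low"),
    high = signal::butter(order, w / nyq, type = "high"),
    pass = signal::butter(order / 2, w / nyq, type = "pass")
  )
  n <- length(x)
  np <- min(n - 1, 500L)
  y <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- iir_filter(flt$b, flt$a, y)
  y <- rev(iir_filter(flt$b, flt$a, rev(y)))
  y[np + seq_len(n)]
}

# Band-limited unit-RMS Gaussian noise (EEG/GSR component synthesis).
band_noise <- function(n, fs, lo, hi) {
  x <- rnorm(n)
  y <- if (lo <= 0) bw_filter(x, fs, hi, "low") else bw_filter(x, fs, c(lo, hi), "pass")
  r <- sqrt(mean(y^2))
  if (r < .Machine$double.eps) stop("degenerate band noise")
  y / r
}

`%||%` <- function(a, b) if (is.null(a)) b else a
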