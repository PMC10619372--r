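#' Zero-phase Butterworth band-pass filter
#'
#' Applies a third-order Butterworth band-pass forward and backward
#' (`signal::filtfilt`), so the output has no phase distortion; the effective
#' magnitude response is that of a sixth-order filter.
#'
#' @param x Numeric vector (one channel).
#' @param band A [band_spec()].
#' @param rate Sampling rate in Hz; must exceed `2 * band$f_hi`.
#' @param order Filter order of the one-pass prototype (default 3).
#' @return Filtered numeric vector, same length as `x`.
#' @examples
#' x <- rnorm(1200)
#' y <- bandpass(x, band_spec("alpha1", 8, 10), rate = 600)
#' @export
bandpass <- function(x, band, rate, order = 3) {
  stopifnot(inherits(band, "band_spec"), is.numeric(x))
  if (rate <= 2 * band$f_hi) {
    stop(sprintf("band %s (up to %g Hz) is above Nyquist for rate %g Hz",
                 band$name, band$f_hi, rate), call. = FALSE)
  }
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x Real numeric vector.
#' @return Complex vector `x + i * H(x)`.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) stop("empty series", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited signal
#'
#' Band-passes `x` and returns the analytic-signal phase. If `band` is NULL,
#' `x` is assumed already band-limited.
#'
#' @inheritParams bandpass
#' @param band Optional [band_spec()]; NULL to skip filtering.
#' @return Numeric vector of phases in `(-pi, pi]`.
#' @export
instantaneous_phase <- function(x, band = NULL, rate = NULL) {
  if (!is.null(band)) x <- bandpass(x, band, rate)
  Arg(analytic_signal(x))
}

# squared magnitude response of the 3rd-order Butterworth band-pass evaluated
# at the n FFT bin frequencies: the zero-phase (forward-backward) response
butter_response_sq <- function(band, rate, n, order = 3) {
  bf <- signal::butter(order, c(band$f_lo, band$f_hi) / (rate / 2), type = "pass")
  z <- exp(-1i * 2 * pi * (0:(n - 1)) / n)
  num <- 0 + 0i; den <- 0 + 0i
  for (cf in bf$b) num <- num * z + cf
  for (cf in bf$a) den <- den * z + cf
  Mod(num / den)^2
}

# one-sided (analytic-signal) doubling mask for length n
hilbert_mask <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  h
}

# phase of the f_low-band component of the f_high-band amplitude envelope;
# the carrier of the PAC estimator chain
envelope_phase <- function(x, f_low, f_high, rate) {
  stopifnot(f_low$f_hi <= f_high$f_lo)
  env <- Mod(analytic_signal(bandpass(x, f_high, rate)))
  Arg(analytic_signal(bandpass(env, f_low, rate)))
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with a Hann taper and constant detrending
#' per segment.
#'
#' @param x Numeric vector.
#' @param rate Sampling rate (Hz).
#' @param seg_s Segment length in seconds (default 2, giving 0.5 Hz bins).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param fmax Highest frequency to keep (Hz).
#' @return A tibble with columns `freq` (Hz) and `power`.
#' @examples
#' w <- welch_psd(sin(2 * pi * 10 * seq(0, 10, by = 1 / 600)), rate = 600)
#' w$freq[which.max(w$power)]
#' @export
welch_psd <- function(x, rate, seg_s = 2, overlap = 0.5, fmax = 90) {
  nseg <- round(seg_s * rate)
  if (length(x) < nseg) stop("recording shorter than one Welch segment", call. = FALSE)
  if (rate < 2 * fmax) stop(sprintf("rate %g Hz cannot resolve %g Hz", rate, fmax), call. = FALSE)
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1) / nseg)
  u <- sum(win^2)
  acc <- 0
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    seg <- (seg - mean(seg)) * win
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / (length(starts) * u * rate)
  nf <- floor(nseg / 2) + 1
  p <- p[seq_len(nf)]
  if (nf > 2) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  freq <- (seq_len(nf) - 1) * rate / nseg
  keep <- freq <= fmax + 1e-9
  tibble(freq = freq[keep], power = p[keep])
}
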