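#' Imaginary phase-locking value
#'
#' `|Im(mean(exp(i * (phi_x - phi_y))))|` with `phi` the analytic-signal phase
#' of the band-passed series. Bounded in `[0, 1]`, symmetric in its arguments,
#' and blind to zero-lag (volume-conduction-like) locking: a zero-lag locked
#' pair scores 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @param band A [band_spec()]; NULL if the inputs are already band-limited.
#' @param rate Sampling rate in Hz (required when `band` is given).
#' @return Scalar in `[0, 1]`.
#' @examples
#' t <- seq(0, 5, by = 1 / 600)
#' iplv(sin(2 * pi * 9 * t), cos(2 * pi * 9 * t))  # quarter-cycle lag -> 1
#' @export
iplv <- function(x, y, band = NULL, rate = NULL) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (var(x) == 0 || var(y) == 0) stop("zero-variance input", call. = FALSE)
  if (!is.null(band)) {
    min_len <- 3 / band$f_lo * rate
    if (length(x) < min_len) {
      stop("series shorter than 3 cycles of the band's lower edge", call. = FALSE)
    }
  }
  px <- instantaneous_phase(x, band, rate)
  py <- instantaneous_phase(y, band, rate)
  abs(Im(mean(exp(1i * (px - py)))))
}

#' Phase-to-amplitude coupling
#'
#' Directed estimator of the modulation of `y`'s high-frequency amplitude
#' envelope by `x`'s low-frequency phase: `y` is band-passed at `f_high`, its
#' analytic envelope is extracted and band-passed at `f_low`, and the
#' imaginary phase-locking value between `x`'s low-band phase and the
#' envelope's low-band phase is returned. `pac(x, y) != pac(y, x)` in general.
#'
#' @param x Phase-bearing (modulating) series.
#' @param y Amplitude-bearing (modulated) series.
#' @param f_low,f_high [band_spec()]s with `f_low$f_hi < f_high$f_lo`.
#' @param rate Sampling rate in Hz.
#' @return Scalar in `[0, 1]`.
#' @export
pac <- function(x, y, f_low, f_high, rate) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (f_low$f_hi > f_high$f_lo) stop("bands overlap: f_low must lie strictly below f_high",
                                     call. = FALSE)
  if (var(x) == 0 || var(y) == 0) stop("zero-variance input", call. = FALSE)
  px <- instantaneous_phase(x, f_low, rate)
  pe <- envelope_phase(y, f_low, f_high, rate)
  abs(Im(mean(exp(1i * (px - pe)))))
}

#' Dynamic functional connectivity graph (4D coupling-strength array)
#'
#' Computes, for every sliding window and region pair, the 8 within-frequency
#' iPLV strengths and the 28 directed cross-frequency PAC strengths. Filtering
#' and analytic phases are computed once on the full series and windowed
#' afterwards, avoiding window-edge filter artifacts. Pooled single-cut
#' surrogate nulls (see [surrogate_config()]) are drawn per mode and one-sided
#' p-values attached, ready for dominant-mode selection with [build_idfcg()].
#'
#' @param x Numeric matrix, samples x ROIs.
#' @param rate Sampling rate in Hz.
#' @param bands List of 8 [band_spec()]s (default [canonical_bands()]).
#' @param window A [window_spec()].
#' @param cfg A [surrogate_config()].
#' @return A `dfcg` object: list with `strengths` and `pvals` (arrays of
#'   dimension 36 x windows x R x R), `nulls` (per-mode sorted pooled null),
#'   `modes` (the [coupling_modes()] table), `windows`, `rate`, `cfg`, and
#'   `reliability_warnings` (modes whose slowest band completes fewer than 3
#'   cycles per window).
#' @export
compute_dfcg <- function(x, rate, bands = canonical_bands(),
                         window = window_spec(), cfg = surrogate_config()) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 ROIs", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in the input series", call. = FALSE)
  if (any(apply(x, 2, var) == 0)) stop("zero-variance ROI series", call. = FALSE)
  duration <- nrow(x) / rate
  win <- sliding_windows(duration, window, rate)
  width_n <- attr(win, "width_samples")

  mt <- coupling_modes(bands)
  slow <- vapply(seq_len(nrow(mt)), function(m) bands[[mt$low[m]]]$f_lo, 0)
  unreliable <- mt$mode[slow * window$width < 3]
  if (length(unreliable) > 0) {
    warning(sprintf(
      "windows of %g s hold < 3 cycles of the slowest band for %d mode(s); phase estimates for these modes are unreliable",
      window$width, length(unreliable)), call. = FALSE)
  }

  R <- ncol(x)
  n <- nrow(x)
  # zero-phase Butterworth band-passing and the analytic signal are applied
  # spectrally in one pass: multiply the FFT by the filter's forward-backward
  # magnitude response and the one-sided doubling mask (periodic boundary)
  X <- stats::mvfft(x)
  hmask <- hilbert_mask(n)
  analytic_bands <- lapply(bands, function(b) {
    stats::mvfft(X * (butter_response_sq(b, rate, n) * hmask),
                 inverse = TRUE) / n
  })
  band_phases <- lapply(analytic_bands, Arg)
  cp <- cross_pairs()
  # envelopes once per (roi, high band), then one low-band filtering per combo
  env_fft <- list()
  for (h in unique(cp[, 2])) {
    env_fft[[as.character(h)]] <- stats::mvfft(Mod(analytic_bands[[h]]))
  }
  env_phases <- lapply(seq_len(nrow(cp)), function(ci) {
    lo <- cp[ci, 1]; hi <- cp[ci, 2]
    Arg(stats::mvfft(env_fft[[as.character(hi)]] *
                       (butter_response_sq(bands[[lo]], rate, n) * hmask),
                     inverse = TRUE) / n)
  })

  core <- dfcg_core_cpp(band_phases, env_phases, cp, win$start, width_n,
                        cfg$n_null, cfg$margin_frac)
  structure(list(
    strengths = core$strengths, pvals = core$pvals, nulls = core$nulls,
    modes = mt, windows = win, window = window, rate = rate, cfg = cfg,
    bands = bands, n_rois = R, reliability_warnings = unreliable
  ), class = "dfcg")
}

#' @export
print.dfcg <- function(x, ...) {
  d <- dim(x$strengths)
  cat(sprintf("<dfcg> %d modes x %d windows x %d x %d ROIs (rate %g Hz)\n",
              d[1], d[2], d[3], d[4], x$rate))
  invisible(x)
}
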