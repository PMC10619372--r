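#' Sliding-window specification
#'
#' @param width Window width in seconds (default 1).
#' @param step Window step in seconds (default 0.1, i.e. 100 ms).
#' @return A `window_spec` object.
#' @examples
#' window_spec(1, 0.1)
#' @export
window_spec <- function(width = 1, step = 0.1) {
  if (!is.finite(width) || width <= 0) stop("width must be positive", call. = FALSE)
  if (!is.finite(step) || step <= 0) stop("step must be positive", call. = FALSE)
  structure(list(width = width, step = step), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> width %g s, step %g s\n", x$width, x$step))
  invisible(x)
}

#' Number of sliding windows for a recording
#'
#' `floor((duration - width) / step) + 1`; for a 300-s recording with 1-s
#' windows stepped every 100 ms this gives 2991 windows.
#'
#' @param duration Recording duration in seconds.
#' @param spec A [window_spec()].
#' @return Integer window count.
#' @export
n_windows <- function(duration, spec = window_spec()) {
  if (duration < spec$width) stop("duration shorter than the window width", call. = FALSE)
  as.integer(floor((duration - spec$width) / spec$step + 1e-9)) + 1L
}

#' Sliding-window sample intervals
#'
#' Returns the half-open sample intervals `[start, end)` (1-based starts,
#' `end` exclusive) of each sliding window, all fully contained in the
#' recording.
#'
#' @inheritParams n_windows
#' @param rate Sampling rate in Hz.
#' @return A tibble with columns `window`, `start`, `end` (sample indices) and
#'   attribute `width_samples`.
#' @examples
#' nrow(sliding_windows(300, window_spec(1, 0.1), rate = 600))  # 2991
#' @export
sliding_windows <- function(duration, spec = window_spec(), rate = 600) {
  nw <- n_windows(duration, spec)
  width_n <- round(spec$width * rate)
  starts <- floor((seq_len(nw) - 1) * spec$step * rate + 1e-9) + 1L
  out <- tibble(window = seq_len(nw), start = as.integer(starts),
                end = as.integer(starts + width_n))
  attr(out, "width_samples") <- as.integer(width_n)
  out
}
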