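#' Frequency band specification
#'
#' A band is a named interval `[f_lo, f_hi]` in Hz. The canonical resting-state
#' analysis uses eight non-overlapping bands from delta to high gamma; see
#' [canonical_bands()].
#'
#' @param name Band label (e.g. `"alpha1"`).
#' @param f_lo,f_hi Band edges in Hz; `0 < f_lo < f_hi`.
#' @return An object of class `band_spec` (a named list with `name`, `f_lo`,
#'   `f_hi`).
#' @examples
#' band_spec("alpha1", 8, 10)
#' @export
band_spec <- function(name, f_lo, f_hi) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo <= 0 || f_hi <= f_lo) {
    stop("band edges must satisfy 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$f_lo, x$f_hi))
  invisible(x)
}

#' The eight canonical frequency bands
#'
#' delta 1-4, theta 4-8, alpha1 8-10, alpha2 10-13, beta1 13-20, beta2 20-30,
#' gamma1 30-45, gamma2 55-90 Hz. The delta lower edge defaults to 1 Hz
#' (matching a 1-Hz acquisition high-pass); pass `delta_lo = 0.5` for the
#' wider convention.
#'
#' @param delta_lo Lower edge of the delta band in Hz.
#' @return A list of 8 [band_spec()] objects, in ascending frequency order.
#' @examples
#' names(canonical_bands())
#' @export
canonical_bands <- function(delta_lo = 1) {
  edges <- list(
    delta  = c(delta_lo, 4),
    theta  = c(4, 8),
    alpha1 = c(8, 10),
    alpha2 = c(10, 13),
    beta1  = c(13, 20),
    beta2  = c(20, 30),
    gamma1 = c(30, 45),
    gamma2 = c(55, 90)
  )
  lapply(stats::setNames(names(edges), names(edges)), function(nm) {
    band_spec(nm, edges[[nm]][1], edges[[nm]][2])
  })
}

#' Coupling-mode table
#'
#' The 36 coupling modes: modes 1-8 are within-frequency phase couplings
#' (delta-delta ... gamma2-gamma2, estimated with iPLV) and modes 9-36 are the
#' 28 cross-frequency phase-to-amplitude couplings, enumerated
#' lexicographically low-band-major (9 = delta-theta, 10 = delta-alpha1, ...,
#' 36 = gamma1-gamma2). Mode 0 is reserved for "no significant coupling".
#'
#' @param bands A list of 8 band specs, as from [canonical_bands()].
#' @return A tibble with columns `mode` (1-36), `type` (`"iplv"`/`"pac"`),
#'   `low` and `high` (band indices), `low_band`, `high_band` (labels), and
#'   `label` (e.g. `"theta->gamma2"`).
#' @examples
#' coupling_modes()
#' @export
coupling_modes <- function(bands = canonical_bands()) {
  stopifnot(length(bands) == 8)
  nm <- vapply(bands, function(b) b$name, "")
  intra <- tibble(
    mode = 1:8, type = "iplv", low = 1:8, high = 1:8,
    low_band = nm, high_band = nm,
    label = paste0(nm, "-", nm)
  )
  cp <- cross_pairs()
  cross <- tibble(
    mode = 9:36, type = "pac", low = cp[, 1], high = cp[, 2],
    low_band = nm[cp[, 1]], high_band = nm[cp[, 2]],
    label = paste0(nm[cp[, 1]], "->", nm[cp[, 2]])
  )
  dplyr::bind_rows(intra, cross)
}

# 28 x 2 matrix of (low, high) band indices, low-band-major order
cross_pairs <- function() {
  p <- which(upper.tri(matrix(0, 8, 8)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("low", "high")
  p
}

#' Map band pairs to mode indices
#'
#' @param low,high Band indices in 1..8; `low == high` gives the
#'   within-frequency mode, `low < high` the cross-frequency mode.
#' @return Integer mode index in 1..36.
#' @examples
#' mode_index(3, 3)  # alpha1-alpha1 -> 3
#' mode_index(2, 8)  # theta->gamma2
#' @export
mode_index <- function(low, high) {
  stopifnot(all(low >= 1 & low <= 8), all(high >= 1 & high <= 8), all(low <= high))
  ifelse(low == high, low,
         8L + (low - 1L) * 8L - (low * (low + 1L)) %/% 2L + high)
}
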