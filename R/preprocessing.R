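#' Screen component time series for artifacts
#'
#' Computes kurtosis, Rényi entropy (order 2) and skewness of each component
#' in sliding windows (default 2 s, non-overlapping), standardizes each metric
#' across windows per component, and counts a window as flagged when all three
#' standardized scores fall outside `z_range`. A component is deemed
#' artifactual when more than `frac` of its windows are flagged. A 5-minute
#' recording at 2-s non-overlapping windows yields 150 evaluated windows.
#'
#' Standardization is robust by default (median and scaled MAD): artifact
#' windows inflate a plain standard deviation so strongly that an artifact
#' cluster can never sit more than `sqrt((1-p)/p)` SDs out (below 2 whenever
#' more than 20% of windows are contaminated), which would make the flagging
#' rule unable to reach its own component criterion. Set `robust = FALSE` for
#' plain z-scores.
#'
#' @param components Numeric matrix, samples x components.
#' @param rate Sampling rate (Hz).
#' @param win_s Window width in seconds (default 2).
#' @param overlap Fractional window overlap (default 0).
#' @param z_range Two-sided z acceptance range (default `c(-2, 2)`).
#' @param frac Flagged-window fraction above which a component is artifactual
#'   (default 0.2).
#' @param robust Use median/MAD standardization (default TRUE).
#' @return A `screening_report` tibble: one row per component with columns
#'   `component`, `n_windows`, `n_flagged`, `artifact`, `reason`; per-window
#'   z-scores in attribute `zscores`.
#' @export
screen_components <- function(components, rate, win_s = 2, overlap = 0,
                              z_range = c(-2, 2), frac = 0.2, robust = TRUE) {
  components <- as.matrix(components)
  n <- nrow(components)
  win_n <- round(win_s * rate)
  if (n < win_n) stop("recording shorter than one screening window", call. = FALSE)
  step <- max(1, round(win_n * (1 - overlap)))
  starts <- seq(1, n - win_n + 1, by = step)
  nw <- length(starts)

  zs <- vector("list", ncol(components))
  rows <- lapply(seq_len(ncol(components)), function(ci) {
    x <- components[, ci]
    if (var(x) == 0) {
      zs[[ci]] <<- matrix(NA_real_, 0, 3)
      return(tibble(component = ci, n_windows = nw, n_flagged = nw,
                    artifact = TRUE, reason = "degenerate"))
    }
    m <- t(vapply(starts, function(s) {
      seg <- x[s:(s + win_n - 1)]
      c(kurt = e1071::kurtosis(seg, type = 1),
        renyi = renyi_entropy(seg),
        skew = e1071::skewness(seg, type = 1))
    }, numeric(3)))
    z <- if (robust) {
      ctr <- apply(m, 2, median)
      scl <- apply(m, 2, stats::mad)
      zero <- scl == 0
      scl[zero] <- apply(m, 2, sd)[zero]
      scale(m, center = ctr, scale = scl)
    } else scale(m)
    z[is.nan(z) | is.infinite(z)] <- 0
    zs[[ci]] <<- z
    flagged <- rowSums(z < z_range[1] | z > z_range[2]) == 3
    nf <- sum(flagged)
    tibble(component = ci, n_windows = nw, n_flagged = nf,
           artifact = nf > frac * nw,
           reason = ifelse(nf > frac * nw, "metric outliers", "clean"))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("screening_report", class(out))
  attr(out, "zscores") <- zs
  out
}

# order-2 (collision) Renyi entropy on a 16-bin histogram over +/- 4 SD
renyi_entropy <- function(x, bins = 16, span = 4) {
  z <- (x - mean(x)) / sd(x)
  z <- pmin(pmax(z, -span), span)
  counts <- tabulate(findInterval(z, seq(-span, span, length.out = bins + 1),
                                  rightmost.closed = TRUE, all.inside = TRUE),
                     nbins = bins)
  p <- counts / sum(counts)
  -log(sum(p^2))
}

#' Functional-interpolation ROI representative
#'
#' Collapses a voxels x samples block to one representative series: each
#' voxel's connectivity strength is the sum of absolute Pearson correlations
#' to the other voxels in the region, strengths are normalized to weights
#' summing to 1, and the representative is the weighted sum of voxel series.
#' A single voxel gets weight 1.
#'
#' @param v Numeric matrix voxels x samples (>= 1 voxel).
#' @return A list with `representative` (numeric vector) and `weights`
#'   (numeric vector summing to 1).
#' @export
roi_representative <- function(v) {
  v <- as.matrix(v)
  if (any(is.na(v))) stop("NaN in voxel series", call. = FALSE)
  k <- nrow(v)
  if (k == 0) stop("need at least one voxel", call. = FALSE)
  if (k == 1) {
    return(list(representative = as.numeric(v[1, ]), weights = 1))
  }
  cm <- abs(cor(t(v)))
  diag(cm) <- 0  # self-terms excluded: they only add a constant
  ss <- rowSums(cm)
  w <- ss / sum(ss)
  list(representative = as.numeric(crossprod(v, w)), weights = as.numeric(w))
}
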