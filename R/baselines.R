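#' Spectral (Welch PSD) profile of one session
#'
#' Welch power spectra per ROI (2-s Hann segments, 50% overlap, constant
#' detrend, 0-90 Hz at 0.5 Hz resolution — 181 bins), optionally restricted to
#' one band, concatenated into a single feature vector.
#'
#' @param x Numeric matrix samples x ROIs.
#' @param rate Sampling rate (Hz); must be at least 180 to reach 90 Hz.
#' @param band Optional [band_spec()]; NULL keeps the full 0-90 Hz range.
#' @return Numeric vector of length `ROIs * bins`.
#' @export
psd_profile <- function(x, rate, band = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2 * rate) stop("recording shorter than 2 s", call. = FALSE)
  if (rate < 180) stop("rate below 180 Hz cannot reach the 90 Hz band edge", call. = FALSE)
  prof <- lapply(seq_len(ncol(x)), function(r) {
    w <- welch_psd(x[, r], rate, seg_s = 2, overlap = 0.5, fmax = 90)
    if (!is.null(band)) w <- w[w$freq >= band$f_lo & w$freq <= band$f_hi, ]
    w$power
  })
  unlist(prof)
}

#' Identification by maximum absolute correlation of feature profiles
#'
#' Each session-1 profile is matched to the session-2 profile with the largest
#' absolute Pearson correlation; accuracy is the fraction of subjects matched
#' to themselves.
#'
#' @param profiles_s1,profiles_s2 Numeric matrices subjects x features (equal
#'   dimensions).
#' @param truth True session-2 index per session-1 subject (identity order by
#'   default).
#' @return A list with `accuracy`, `assignment` (predicted session-2 index per
#'   session-1 subject), and `correct` (0/1 vector).
#' @export
correlation_match <- function(profiles_s1, profiles_s2,
                              truth = seq_len(nrow(profiles_s1))) {
  p1 <- as.matrix(profiles_s1); p2 <- as.matrix(profiles_s2)
  if (ncol(p1) != ncol(p2)) stop("feature dimensions differ", call. = FALSE)
  if (any(apply(p1, 1, sd) == 0) || any(apply(p2, 1, sd) == 0)) {
    stop("zero-variance profile", call. = FALSE)
  }
  cc <- abs(cor(t(p1), t(p2)))
  assignment <- apply(cc, 1, which.max)
  correct <- as.integer(assignment == truth)
  list(accuracy = mean(correct), assignment = assignment, correct = correct)
}

#' Static frequency-dependent connectome profile
#'
#' Whole-recording iPLV per region pair in one band, upper triangle
#' vectorized row-major (length `R*(R-1)/2`; 4005 at 90 ROIs).
#'
#' @param x Numeric matrix samples x ROIs.
#' @param rate Sampling rate (Hz).
#' @param band A [band_spec()].
#' @return Numeric vector of pairwise static iPLV values.
#' @export
static_fc_profile <- function(x, rate, band) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 ROIs", call. = FALSE)
  ph <- apply(x, 2, function(col) Arg(analytic_signal(bandpass(col, band, rate))))
  pr <- pair_table(ncol(x))
  vapply(seq_len(nrow(pr)), function(k) {
    abs(Im(mean(exp(1i * (ph[, pr[k, 1]] - ph[, pr[k, 2]])))))
  }, 0)
}

#' Identification from dynamic coupling-strength matrices
#'
#' Flattens each subject's iDFCG strength stack to a windows x pairs matrix
#' and matches session-1 subjects to the session-2 subject at minimum
#' Euclidean distance.
#'
#' @param idfcg_s1,idfcg_s2 Lists (over subjects) of `idfcg` objects or
#'   windows x pairs strength matrices of equal shape.
#' @return A list with `accuracy` and `assignment`.
#' @export
dynamic_strength_match <- function(idfcg_s1, idfcg_s2) {
  flat <- function(obj) {
    if (inherits(obj, "idfcg")) {
      seqs <- docm_sequences(obj)
      pr <- attr(seqs, "pairs")
      m <- vapply(seq_len(nrow(pr)),
                  function(k) obj$strengths[, pr[k, 1], pr[k, 2]],
                  numeric(dim(obj$strengths)[1]))
      as.numeric(m)
    } else as.numeric(obj)
  }
  f1 <- lapply(idfcg_s1, flat); f2 <- lapply(idfcg_s2, flat)
  if (length(unique(vapply(c(f1, f2), length, 0L))) != 1) {
    stop("shape mismatch between strength stacks", call. = FALSE)
  }
  n <- length(f1)
  assignment <- vapply(seq_len(n), function(i) {
    d <- vapply(seq_along(f2), function(j) sqrt(sum((f1[[i]] - f2[[j]])^2)), 0)
    which.min(d)
  }, 0L)
  list(accuracy = mean(assignment == seq_len(n)), assignment = assignment)
}

#' Random edge-subset identification control
#'
#' Draws `n_draws` random edge sets of size `k` (without replacement within a
#' draw) from the edge universe and scores summed-log-likelihood
#' identification for each, summarizing the accuracy distribution.
#'
#' @param cube Array from [edge_loglik_cube()].
#' @param k Edges per draw.
#' @param n_draws Number of random draws.
#' @param seed Optional seed.
#' @return A list with `mean`, `sd`, and `accuracies` (length `n_draws`).
#' @export
random_subset_control <- function(cube, k, n_draws = 1000, seed = NULL) {
  E <- dim(cube)[1]
  if (k > E) stop("k exceeds the edge universe", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  acc <- vapply(seq_len(n_draws), function(d) {
    sel <- sample(E, k)
    loglik_accuracy(apply(cube[sel, , , drop = FALSE], c(2, 3), sum))
  }, 0)
  list(mean = mean(acc), sd = sd(acc), accuracies = acc)
}
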