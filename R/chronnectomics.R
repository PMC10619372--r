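#' Comodulogram of a DoCM label sequence
#'
#' Tabulates the probability distribution of dominant coupling modes across
#' time for one region pair, arranged as an 8 x 8 matrix: the diagonal holds
#' the within-frequency modes, the upper off-diagonal cell (row = modulating /
#' low band, column = modulated / high band) the cross-frequency modes.
#' Probabilities are taken over the windows with a nonzero label (a zero label
#' means "no coupling", not a 37th mode), so the entries sum to 1 whenever any
#' coupling exists; an all-zero sequence yields the zero matrix (flagged via
#' attribute `empty`).
#'
#' @param seq Integer vector of DoCM labels in 0..36.
#' @param bands Band definitions (for dimnames).
#' @return An 8 x 8 matrix of class `comodulogram`.
#' @export
comodulogram <- function(seq, bands = canonical_bands()) {
  seq <- as.integer(seq)
  if (any(seq < 0 | seq > 36)) stop("labels must be in 0..36", call. = FALSE)
  nm <- vapply(bands, function(b) b$name, "")
  cm <- matrix(0, 8, 8, dimnames = list(modulating = nm, modulated = nm))
  nz <- seq[seq > 0]
  if (length(nz) > 0) {
    tab <- tabulate(nz, nbins = 36) / length(nz)
    cm[cbind(1:8, 1:8)] <- tab[1:8]
    cp <- cross_pairs()
    cm[cp] <- tab[9:36]
  }
  structure(cm, class = c("comodulogram", "matrix"), empty = length(nz) == 0)
}

#' @export
tidy.comodulogram <- function(x, ...) {
  nm <- rownames(x)
  tibble(
    modulating = rep(nm, 8), modulated = rep(nm, each = 8),
    probability = as.numeric(x)
  )
}

#' Flexibility index of DoCM label sequences
#'
#' For each region pair, the fraction of consecutive-window transitions in
#' which the dominant coupling mode changes:
#' `FI(i,j) = (1/(T-1)) * sum_t 1[label_t != label_{t+1}]`, so `FI` lies in
#' `[0, 1]` (0 = perfectly stable, 1 = changes at every step). The global
#' index averages FI over the `R*(R-1)/2` region pairs.
#'
#' @param labels Integer array windows x R x R (as in an `idfcg`), or an
#'   `idfcg` object.
#' @return A `flexibility` object: list with `fi` (R x R matrix) and
#'   `fi_global` (scalar).
#' @examples
#' flexibility_index(array(c(1, 1, 2, 2, 3), c(5, 1, 1)))
#' @export
flexibility_index <- function(labels) {
  if (inherits(labels, "idfcg")) labels <- labels$labels
  d <- dim(labels)
  if (is.null(d) || length(d) != 3) stop("labels must be a windows x R x R array", call. = FALSE)
  T_ <- d[1]; R <- d[2]
  if (T_ < 2) stop("need at least 2 windows", call. = FALSE)
  changes <- labels[-1, , , drop = FALSE] != labels[-T_, , , drop = FALSE]
  fi <- apply(changes, c(2, 3), mean)
  ut <- upper.tri(fi)
  structure(list(fi = fi, fi_global = mean(fi[ut])), class = "flexibility")
}

#' @export
print.flexibility <- function(x, ...) {
  cat(sprintf("<flexibility> %d ROIs, global FI %.4f\n", nrow(x$fi), x$fi_global))
  invisible(x)
}

#' @export
tidy.flexibility <- function(x, ...) {
  pr <- pair_table(nrow(x$fi))
  tibble(roi_i = pr[, 1], roi_j = pr[, 2], fi = x$fi[pr])
}

# intraclass correlation ICC(2,1), two-way random effects, absolute agreement
icc21 <- function(x, y) {
  n <- length(x); k <- 2
  dat <- cbind(x, y)
  ms_r <- k * var(rowMeans(dat))
  ms_c <- n * var(colMeans(dat))
  grand <- mean(dat)
  ss_tot <- sum((dat - grand)^2)
  ss_r <- k * sum((rowMeans(dat) - grand)^2)
  ss_c <- n * sum((colMeans(dat) - grand)^2)
  ms_e <- (ss_tot - ss_r - ss_c) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
}

#' Optimize sliding-window parameters by flexibility-index repeatability
#'
#' Runs the full dominant-coupling-mode pipeline on both sessions of every
#' subject for each (width, step) grid point, computes the pairwise
#' flexibility index, and scores repeatability as the Pearson correlation of
#' the pooled pairwise FI between sessions (across subjects and pairs);
#' ICC(2,1) is reported alongside. The default grids span widths 0.5-3 s and
#' steps 50-500 ms (110 grid points).
#'
#' @param cohort A two-session `docm_cohort`.
#' @param widths Window widths in seconds.
#' @param steps Window steps in seconds.
#' @param cfg A [surrogate_config()].
#' @return A `window_opt` object: list with `best_width`, `best_step`, and
#'   `surface` (tibble with width, step, repeatability, icc).
#' @export
optimize_window_params <- function(cohort,
                                   widths = seq(0.5, 3, by = 0.25),
                                   steps = seq(0.05, 0.5, by = 0.05),
                                   cfg = surrogate_config()) {
  stopifnot(inherits(cohort, "docm_cohort"))
  if (length(widths) == 0 || length(steps) == 0) stop("empty grid", call. = FALSE)
  if (any(widths > cohort$duration)) {
    stop("grid width exceeds the recording length", call. = FALSE)
  }
  grid <- expand.grid(width = widths, step = steps)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    ws <- window_spec(grid$width[g], grid$step[g])
    fis <- lapply(seq_along(cohort$subjects), function(s) {
      lapply(cohort$subjects[[s]]$sessions[1:2], function(x) {
        # fix the surrogate draws per (grid point, subject) so both sessions
        # face the same null and the surface is deterministic given the cohort
        set.seed((g * 131071L + s * 8191L) %% .Machine$integer.max)
        idf <- build_idfcg(compute_dfcg(x, cohort$rate, window = ws, cfg = cfg))
        fi <- flexibility_index(idf)
        fi$fi[upper.tri(fi$fi)]
      })
    })
    f1 <- unlist(lapply(fis, `[[`, 1))
    f2 <- unlist(lapply(fis, `[[`, 2))
    rep_r <- if (sd(f1) == 0 && sd(f2) == 0 && all(f1 == f2)) 1
             else if (sd(f1) == 0 || sd(f2) == 0) 0
             else cor(f1, f2)
    tibble(width = grid$width[g], step = grid$step[g],
           repeatability = rep_r, icc = icc21(f1, f2))
  })
  surface <- dplyr::bind_rows(res)
  best <- surface[which.max(surface$repeatability), ]
  structure(list(best_width = best$width, best_step = best$step,
                 surface = surface), class = "window_opt")
}

#' @export
print.window_opt <- function(x, ...) {
  cat(sprintf("<window_opt> best width %g s, step %g s (repeatability %.3f)\n",
              x$best_width, x$best_step,
              max(x$surface$repeatability)))
  invisible(x)
}
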