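#' Select the dominant coupling mode from a 36-vector of p-values
#'
#' The survivor set is every mode with `p < alpha / bonferroni_k`. With one
#' survivor, it wins; with several, the highest strength wins (ties broken by
#' lowest p, then lowest mode index); with none, the pair is labelled 0.
#'
#' @param p Numeric vector of 36 one-sided p-values (mode axis order of
#'   [coupling_modes()]).
#' @param strength Numeric vector of 36 coupling strengths in `[0, 1]`.
#' @param cfg A [surrogate_config()].
#' @return A list with `label` (0-36), `strength`, and `p` (the winner's
#'   p-value; 1 when no survivor).
#' @export
select_dominant <- function(p, strength, cfg = surrogate_config()) {
  if (length(p) != length(strength)) stop("p and strength lengths differ", call. = FALSE)
  if (any(is.na(p))) stop("NaN p-values", call. = FALSE)
  thr <- cfg$alpha / cfg$bonferroni_k
  surv <- which(p < thr)
  if (length(surv) == 0) return(list(label = 0L, strength = 0, p = 1))
  ord <- surv[order(-strength[surv], p[surv], surv)]
  w <- ord[1]
  list(label = as.integer(w), strength = strength[w], p = p[w])
}

#' Resolve the two orientations of a region pair
#'
#' Cross-frequency coupling is directed, so each unordered pair `{i, j}` has
#' two candidate dominant modes. The orientation with the lower p-value wins;
#' on a p tie, the higher strength. Two zero labels resolve to zero.
#'
#' @param edge_ij,edge_ji Lists with `label`, `strength`, `p` (as returned by
#'   [select_dominant()]) from the same window.
#' @return A list with `label`, `strength`, `p`.
#' @export
resolve_symmetry <- function(edge_ij, edge_ji) {
  if (edge_ij$label == 0 && edge_ji$label == 0) {
    return(list(label = 0L, strength = 0, p = 1))
  }
  if (edge_ij$p < edge_ji$p) return(edge_ij)
  if (edge_ji$p < edge_ij$p) return(edge_ji)
  if (edge_ij$strength >= edge_ji$strength) edge_ij else edge_ji
}

#' Per-window Benjamini-Hochberg filter across the network
#'
#' Applies BH independently per window (row) to the dominant-mode p-values of
#' all region pairs and returns the logical acceptance mask. `NA` entries are
#' never accepted.
#'
#' @param dominant_p Numeric matrix, windows x pairs.
#' @param q False-discovery level.
#' @return Logical matrix of the same shape; TRUE where the edge survives.
#' @export
fdr_filter <- function(dominant_p, q = 0.01) {
  dominant_p <- as.matrix(dominant_p)
  mask <- matrix(FALSE, nrow(dominant_p), ncol(dominant_p))
  for (w in seq_len(nrow(dominant_p))) {
    p <- dominant_p[w, ]
    ok <- !is.na(p)
    if (!any(ok)) next
    mask[w, ok] <- p.adjust(p[ok], method = "BH") <= q
  }
  mask
}

#' Integrated dynamic functional connectivity graph (iDFCG)
#'
#' Composes dominant-mode selection over a computed [compute_dfcg()] stack:
#' per window and ordered region pair the Bonferroni-filtered survivor set is
#' reduced to one candidate mode; the two orientations of each pair are
#' resolved to an undirected edge; and a per-window Benjamini-Hochberg filter
#' across the network resets edges that do not survive at `fdr_q`. The result
#' pairs a strength array with an integer label array (0 = no significant
#' coupling, 1-36 = the dominant coupling mode).
#'
#' @param dfcg A `dfcg` object from [compute_dfcg()].
#' @param cfg A [surrogate_config()]; defaults to the one stored in `dfcg`.
#' @return An `idfcg` object: list with `strengths` and `labels` (arrays of
#'   dimension windows x R x R, symmetric), `pmat` (windows x R x R dominant
#'   p-values), `modes`, `windows`, `window`, `rate`, `cfg`.
#' @export
build_idfcg <- function(dfcg, cfg = NULL) {
  stopifnot(inherits(dfcg, "dfcg"))
  if (is.null(cfg)) cfg <- dfcg$cfg
  d <- dim(dfcg$strengths)
  n_modes <- d[1]; nw <- d[2]; R <- d[3]
  thr <- cfg$alpha / cfg$bonferroni_k

  # flatten mode axis: 36 x (windows * R * R)
  sflat <- matrix(dfcg$strengths, nrow = n_modes)
  pflat <- matrix(dfcg$pvals, nrow = n_modes)
  surv <- pflat < thr
  key <- ifelse(surv, sflat, -Inf)
  n_surv <- colSums(surv)
  winner <- max.col(t(key), ties.method = "first")
  cells <- cbind(winner, seq_along(winner))
  lab <- ifelse(n_surv > 0, winner, 0L)
  str <- ifelse(n_surv > 0, sflat[cells], 0)
  pv  <- ifelse(n_surv > 0, pflat[cells], 1)

  lab <- array(as.integer(lab), dim = c(nw, R, R))
  str <- array(str, dim = c(nw, R, R))
  pv  <- array(pv, dim = c(nw, R, R))

  # orientation resolution: lower p wins, tie -> higher strength
  labs <- array(0L, dim = c(nw, R, R))
  strs <- array(0, dim = c(nw, R, R))
  ps   <- array(1, dim = c(nw, R, R))
  for (i in seq_len(R - 1)) {
    for (j in (i + 1):R) {
      pij <- pv[, i, j]; pji <- pv[, j, i]
      take_ij <- pij < pji | (pij == pji & str[, i, j] >= str[, j, i])
      l <- ifelse(take_ij, lab[, i, j], lab[, j, i])
      s <- ifelse(take_ij, str[, i, j], str[, j, i])
      p <- ifelse(take_ij, pij, pji)
      zero <- lab[, i, j] == 0 & lab[, j, i] == 0
      l[zero] <- 0L; s[zero] <- 0; p[zero] <- 1
      labs[, i, j] <- l; labs[, j, i] <- l
      strs[, i, j] <- s; strs[, j, i] <- s
      ps[, i, j] <- p; ps[, j, i] <- p
    }
  }

  # per-window FDR across the network's dominant p-values (upper triangle)
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  pm <- matrix(ps[cbind(rep(seq_len(nw), nrow(ut)),
                        rep(ut[, 1], each = nw),
                        rep(ut[, 2], each = nw))], nrow = nw)
  keep <- fdr_filter(pm, q = cfg$fdr_q)
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    drop <- !keep[, k] & labs[, i, j] != 0L
    if (any(drop)) {
      labs[drop, i, j] <- 0L; labs[drop, j, i] <- 0L
      strs[drop, i, j] <- 0; strs[drop, j, i] <- 0
      ps[drop, i, j] <- 1; ps[drop, j, i] <- 1
    }
  }

  structure(list(strengths = strs, labels = labs, pmat = ps,
                 modes = dfcg$modes, windows = dfcg$windows,
                 window = dfcg$window, rate = dfcg$rate, cfg = cfg,
                 n_rois = R), class = "idfcg")
}

#' @export
print.idfcg <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<idfcg> %d windows x %d x %d ROIs; %.1f%% of pair-windows labelled\n",
              d[1], d[2], d[3], 100 * nonzero_fraction(x)))
  invisible(x)
}

#' Fraction of labelled pair-windows of an iDFCG
#'
#' @param idfcg An `idfcg` object.
#' @return Scalar in `[0, 1]`: the fraction of (window, pair) cells with a
#'   nonzero dominant-mode label (upper triangle only).
#' @export
nonzero_fraction <- function(idfcg) {
  mean(docm_sequences(idfcg) != 0)
}

#' DoCM label sequence of one region pair
#'
#' @param idfcg An `idfcg` object.
#' @param i,j ROI indices.
#' @return Integer vector over windows (0 = no significant coupling).
#' @export
docm_sequence <- function(idfcg, i, j) {
  stopifnot(inherits(idfcg, "idfcg"))
  as.integer(idfcg$labels[, i, j])
}

#' All DoCM label sequences (windows x pairs matrix)
#'
#' Columns follow the row-major upper triangle: (1,2), (1,3), ..., (R-1,R).
#'
#' @param idfcg An `idfcg` object.
#' @return Integer matrix windows x `R*(R-1)/2`, with attribute `pairs`
#'   (2-column matrix of ROI indices).
#' @export
docm_sequences <- function(idfcg) {
  R <- idfcg$n_rois
  pr <- pair_table(R)
  out <- vapply(seq_len(nrow(pr)),
                function(k) idfcg$labels[, pr[k, 1], pr[k, 2]],
                integer(dim(idfcg$labels)[1]))
  out <- matrix(as.integer(out), nrow = dim(idfcg$labels)[1])
  attr(out, "pairs") <- pr
  out
}

# row-major upper-triangle pair enumeration
pair_table <- function(R) {
  p <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  colnames(p) <- c("i", "j")
  p
}

#' @export
tidy.idfcg <- function(x, ...) {
  seqs <- docm_sequences(x)
  pr <- attr(seqs, "pairs")
  nw <- nrow(seqs)
  strs <- vapply(seq_len(nrow(pr)),
                 function(k) x$strengths[, pr[k, 1], pr[k, 2]], numeric(nw))
  tibble(
    window = rep(seq_len(nw), times = nrow(pr)),
    roi_i = rep(pr[, 1], each = nw),
    roi_j = rep(pr[, 2], each = nw),
    label = as.integer(seqs),
    mode = c("none", x$modes$label)[as.integer(seqs) + 1L],
    strength = as.numeric(strs)
  )
}

#' @export
glance.idfcg <- function(x, ...) {
  tibble(
    n_windows = dim(x$labels)[1], n_rois = x$n_rois,
    frac_labelled = nonzero_fraction(x),
    alpha = x$cfg$alpha, bonferroni_k = x$cfg$bonferroni_k,
    fdr_q = x$cfg$fdr_q, n_null = x$cfg$n_null
  )
}
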