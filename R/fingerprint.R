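#' DoCM label sequences for every subject of a cohort
#'
#' Runs the full dominant-coupling-mode pipeline (band-limited phases, sliding
#' windows, pooled surrogate filtering) on one session of every subject and
#' returns the per-edge label sequences.
#'
#' @param cohort A `docm_cohort`.
#' @param session Session index.
#' @param window A [window_spec()].
#' @param cfg A [surrogate_config()].
#' @param verbose Print progress.
#' @return List over subjects of windows x pairs integer label matrices;
#'   attribute `pairs` maps columns to ROI pairs and attribute `strengths`
#'   holds the matching windows x pairs dominant-coupling strength matrix.
#' @export
cohort_docm_sequences <- function(cohort, session = 1, window = window_spec(),
                                  cfg = surrogate_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "docm_cohort"))
  lapply(seq_along(cohort$subjects), function(s) {
    if (verbose) message(sprintf("DoCM pipeline: subject %d session %d", s, session))
    x <- cohort$subjects[[s]]$sessions[[session]]
    idf <- build_idfcg(compute_dfcg(x, cohort$rate, window = window, cfg = cfg))
    seqs <- docm_sequences(idf)
    pr <- attr(seqs, "pairs")
    attr(seqs, "strengths") <- vapply(
      seq_len(nrow(pr)), function(k) idf$strengths[, pr[k, 1], pr[k, 2]],
      numeric(nrow(seqs)))
    seqs
  })
}

#' Train per-subject, per-edge discrete HMMs
#'
#' @param train_seqs List over subjects of windows x pairs label matrices
#'   (from [cohort_docm_sequences()]).
#' @param state_grid Candidate state counts (see [fit_dhmm()]).
#' @param seed Seed for EM restarts.
#' @param ... Passed to [fit_dhmm()].
#' @return List over subjects of lists over edges of `dhmm` models.
#' @export
fit_edge_models <- function(train_seqs, state_grid = 2:3, seed = 1, ...) {
  lapply(seq_along(train_seqs), function(k) {
    m <- train_seqs[[k]]
    lapply(seq_len(ncol(m)), function(e) {
      sub_seed <- as.integer((as.numeric(seed) * 100003 + k * 1009 + e) %%
                               2147483647)
      suppressWarnings(
        fit_dhmm(m[, e], state_grid = state_grid, seed = sub_seed, ...))
    })
  })
}

#' Edge-wise log-likelihood cube
#'
#' `cube[e, k, m]` = log-likelihood of test subject `m`'s label sequence on
#' edge `e` under training subject `k`'s model for that edge. All
#' identification, ranking, stepwise-selection, similarity and random-subset
#' computations derive from this cube.
#'
#' @param models Output of [fit_edge_models()].
#' @param test_seqs List over test subjects of windows x pairs label matrices.
#' @return Numeric array edges x train-subjects x test-subjects.
#' @export
edge_loglik_cube <- function(models, test_seqs) {
  K <- length(models)
  M <- length(test_seqs)
  E <- length(models[[1]])
  if (ncol(test_seqs[[1]]) != E) stop("edge count mismatch", call. = FALSE)
  cube <- array(NA_real_, c(E, K, M))
  for (k in seq_len(K)) {
    if (length(models[[k]]) != E) stop("missing model", call. = FALSE)
    for (e in seq_len(E)) {
      mod <- models[[k]][[e]]
      for (m in seq_len(M)) {
        cube[e, k, m] <- dhmm_loglik(mod, test_seqs[[m]][, e])
      }
    }
  }
  cube
}

# accuracy of argmax-classification given a train x test loglik matrix,
# assuming test subject m's true class is m; ties -> lowest index
loglik_accuracy <- function(ll) {
  pred <- apply(ll, 2, which.max)
  mean(pred == seq_len(ncol(ll)))
}

#' Rank edges by single-edge identification accuracy
#'
#' Every test subject is classified by the training model with the highest
#' log-likelihood on that edge alone; the edge score is the resulting
#' identification accuracy. Ranking is descending with ties broken by lower
#' edge index. With a single subject every accuracy is trivially 1 (a
#' degenerate-ranking warning is raised).
#'
#' @param cube Array from [edge_loglik_cube()].
#' @return A tibble with `edge`, `accuracy`, `rank`, sorted by rank.
#' @export
rank_edges <- function(cube) {
  E <- dim(cube)[1]
  if (dim(cube)[2] == 1) {
    warning("single subject: per-edge accuracies are degenerate", call. = FALSE)
  }
  acc <- vapply(seq_len(E), function(e) {
    loglik_accuracy(matrix(cube[e, , ], dim(cube)[2], dim(cube)[3]))
  }, 0)
  if (dim(cube)[2] == 1) acc <- rep(1, E)
  ord <- order(-acc, seq_len(E))
  tibble(edge = ord, accuracy = acc[ord], rank = seq_len(E))
}

#' Step-wise greedy edge aggregation
#'
#' Walks the ranked edge list, accumulating an edge only when the summed
#' log-likelihood classification accuracy over the retained set strictly
#' improves; stops at 100% accuracy or after `plateau_patience` consecutive
#' non-improving candidates. The retained accuracy curve is non-decreasing by
#' construction.
#'
#' @param ranked Tibble from [rank_edges()] (or an integer vector of edges in
#'   rank order).
#' @param cube Array from [edge_loglik_cube()].
#' @param plateau_patience Non-improving candidates tolerated before stopping.
#' @return A `stepwise_selection` object: list with `edges` (selected, in
#'   inclusion order), `curve` (tibble: step, edge, accuracy), `accuracy`.
#' @export
stepwise_select <- function(ranked, cube, plateau_patience = 5) {
  edges <- if (is.data.frame(ranked)) ranked$edge else as.integer(ranked)
  if (length(edges) == 0) stop("empty ranked list", call. = FALSE)
  K <- dim(cube)[2]; M <- dim(cube)[3]
  sel <- integer(0)
  acc <- 0
  ll_sum <- matrix(0, K, M)
  curve <- list()
  stale <- 0
  for (e in edges) {
    cand <- ll_sum + matrix(cube[e, , ], K, M)
    a <- loglik_accuracy(cand)
    if (a > acc) {
      sel <- c(sel, e)
      ll_sum <- cand
      acc <- a
      stale <- 0
      curve[[length(curve) + 1]] <- tibble(step = length(sel), edge = e,
                                           accuracy = acc)
    } else {
      stale <- stale + 1
    }
    if (acc >= 1 || stale >= plateau_patience) break
  }
  structure(list(edges = sel, curve = dplyr::bind_rows(curve), accuracy = acc),
            class = "stepwise_selection")
}

#' @export
print.stepwise_selection <- function(x, ...) {
  cat(sprintf("<stepwise_selection> %d edges, accuracy %.1f%%\n",
              length(x$edges), 100 * x$accuracy))
  invisible(x)
}

#' Similarity matrix of summed log-likelihoods
#'
#' Entry (k, m) is the sum over the selected edge set of the log-likelihood of
#' test subject m's DoCM sequences under training subject k's models.
#'
#' @param cube Array from [edge_loglik_cube()].
#' @param edge_set Integer vector of edges.
#' @return A train x test matrix of class `similarity_matrix`.
#' @export
similarity_matrix <- function(cube, edge_set) {
  if (length(edge_set) == 0) stop("empty edge set", call. = FALSE)
  sl <- cube[edge_set, , , drop = FALSE]
  out <- apply(sl, c(2, 3), sum)
  structure(out, class = c("similarity_matrix", "matrix"))
}

#' @export
tidy.similarity_matrix <- function(x, ...) {
  tibble(train = rep(seq_len(nrow(x)), ncol(x)),
         test = rep(seq_len(ncol(x)), each = nrow(x)),
         sum_loglik = as.numeric(x),
         self = rep(seq_len(nrow(x)), ncol(x)) == rep(seq_len(ncol(x)), each = nrow(x)))
}

#' Learn match/non-match thresholds from a similarity matrix
#'
#' Summarizes the diagonal (self) and off-diagonal (cross) summed
#' log-likelihoods as mean +/- sd and derives a decision cutoff halfway
#' between the largest off-diagonal and the smallest diagonal score. The
#' cross-subject scores are strongly left-skewed (a wrong model can be
#' arbitrarily unlikely), so the gap between the two distributions' facing
#' extremes — not a multiple of the off-diagonal SD — defines separability; if
#' the distributions interleave the cohort is declared non-separable.
#'
#' @param sim A square `similarity_matrix` with meaningful diagonal.
#' @return A `match_decision` object: list with `threshold_off` (mean, sd),
#'   `threshold_diag` (mean, sd), `cutoff`.
#' @export
learn_thresholds <- function(sim) {
  sim <- unclass(sim)
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square", call. = FALSE)
  dg <- diag(sim)
  off <- sim[row(sim) != col(sim)]
  lo <- max(off)
  hi <- min(dg)
  if (lo >= hi) stop("cohort not separable: score distributions interleave", call. = FALSE)
  structure(list(threshold_off = c(mean = mean(off), sd = sd(off)),
                 threshold_diag = c(mean = mean(dg), sd = sd(dg)),
                 cutoff = (lo + hi) / 2), class = "match_decision")
}

#' @export
print.match_decision <- function(x, ...) {
  cat(sprintf(
    "<match_decision> off-diagonal %.2f +/- %.2f, diagonal %.2f +/- %.2f, cutoff %.2f\n",
    x$threshold_off["mean"], x$threshold_off["sd"],
    x$threshold_diag["mean"], x$threshold_diag["sd"], x$cutoff))
  invisible(x)
}

#' @export
glance.match_decision <- function(x, ...) {
  tibble(off_mean = unname(x$threshold_off["mean"]),
         off_sd = unname(x$threshold_off["sd"]),
         diag_mean = unname(x$threshold_diag["mean"]),
         diag_sd = unname(x$threshold_diag["sd"]),
         cutoff = x$cutoff)
}

#' Match training subjects against an external cohort
#'
#' For each training (cohort-1) subject, the summed log-likelihood against
#' every cohort-2 subject is computed over the selected edge set; a match is
#' declared when the maximum exceeds the learned cutoff, and the matched
#' identity is the argmax.
#'
#' @param cube2 Array from [edge_loglik_cube()] (training models x cohort-2
#'   sequences).
#' @param edge_set Selected edges.
#' @param decision A `match_decision` from [learn_thresholds()].
#' @return An `external_match` object: list with `matches` (tibble:
#'   cohort1_id, cohort2_id, score), `scores` (similarity matrix), `cutoff`.
#' @export
external_match <- function(cube2, edge_set, decision) {
  sim <- similarity_matrix(cube2, edge_set)
  best <- apply(sim, 1, which.max)
  best_score <- sim[cbind(seq_len(nrow(sim)), best)]
  hit <- best_score > decision$cutoff
  matches <- tibble(cohort1_id = which(hit), cohort2_id = best[hit],
                    score = best_score[hit])
  structure(list(matches = matches, scores = sim, cutoff = decision$cutoff),
            class = "external_match")
}

#' @export
print.external_match <- function(x, ...) {
  cat(sprintf("<external_match> %d matches above cutoff %.2f\n",
              nrow(x$matches), x$cutoff))
  invisible(x)
}

#' Differentiability score
#'
#' Z-score of a subject's self-match similarity against the distribution of
#' their cross-subject similarities: `(self - mean(others)) / sd(others)`.
#' When no self entry exists, the maximum entry plays the role of self.
#'
#' @param scores Numeric vector: one training subject's summed log-likelihoods
#'   against all test subjects.
#' @param self Index of the self entry, or NULL.
#' @return Scalar differentiability score.
#' @export
differentiability <- function(scores, self = NULL) {
  if (is.null(self)) {
    self <- which.max(scores)
  }
  others <- scores[-self]
  if (length(others) < 3) stop("need at least 3 non-self entries", call. = FALSE)
  s <- sd(others)
  if (s == 0) stop("zero spread among non-self scores", call. = FALSE)
  (scores[self] - mean(others)) / s
}

#' Identification accuracy within and between subnetworks
#'
#' Partitions the edge universe by a 5-network ROI map into 5 within-network
#' and 10 between-network groups (15 runs) and scores summed-log-likelihood
#' identification per group.
#'
#' @param cube Array from [edge_loglik_cube()], with `pairs` the ROI pair per
#'   edge.
#' @param pairs Integer matrix edges x 2 of ROI indices.
#' @param map Character (or factor) vector: network label per ROI; exactly 5
#'   distinct labels; every ROI mapped (no NA).
#' @return A tibble with `group`, `type` (within/between), `n_edges`,
#'   `accuracy` (NA when a group has no edges).
#' @export
subnetwork_performance <- function(cube, pairs, map) {
  if (any(is.na(map))) stop("every ROI must be mapped to a network", call. = FALSE)
  nets <- sort(unique(as.character(map)))
  if (length(nets) != 5) stop("expected exactly 5 network labels", call. = FALSE)
  groups <- list()
  for (a in seq_along(nets)) {
    for (b in a:length(nets)) {
      nm <- if (a == b) paste0("within-", nets[a])
            else paste0(nets[a], "-", nets[b])
      sel <- which((map[pairs[, 1]] == nets[a] & map[pairs[, 2]] == nets[b]) |
                   (map[pairs[, 1]] == nets[b] & map[pairs[, 2]] == nets[a]))
      groups[[nm]] <- list(type = if (a == b) "within" else "between", sel = sel)
    }
  }
  dplyr::bind_rows(lapply(names(groups), function(nm) {
    g <- groups[[nm]]
    acc <- if (length(g$sel) == 0) NA_real_ else {
      loglik_accuracy(apply(cube[g$sel, , , drop = FALSE], c(2, 3), sum))
    }
    tibble(group = nm, type = g$type, n_edges = length(g$sel), accuracy = acc)
  }))
}
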