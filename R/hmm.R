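#' Epoch-wise probability-distribution feature matrix
#'
#' Splits a DoCM label sequence into six epochs and tabulates, per epoch, the
#' empirical frequency of each nonzero label among the epoch's windows. At the
#' full scale of 2991 windows the epochs are 500, 500, 500, 500, 500 and 491
#' windows; shorter sequences use an epoch width rounded up to a multiple of
#' ten windows (falling back to an even six-way split when five such epochs
#' would exhaust the sequence). Rows sum to at most 1: windows with label 0
#' contribute to the denominator but to no column.
#'
#' @param seq Integer vector of DoCM labels (length >= 6).
#' @param n_epochs Number of epochs (default 6).
#' @return A 6 x 36 matrix of class `pd_features`, attribute `epoch_sizes`;
#'   attribute `empty` is TRUE when no nonzero label exists.
#' @export
pd_feature_matrix <- function(seq, n_epochs = 6) {
  seq <- as.integer(seq)
  T_ <- length(seq)
  if (T_ < n_epochs) stop("sequence shorter than the number of epochs", call. = FALSE)
  s <- 10L * as.integer(ceiling(T_ / (10 * n_epochs)))
  if ((n_epochs - 1) * s >= T_) s <- as.integer(ceiling(T_ / n_epochs))
  bounds <- pmin(s * seq_len(n_epochs), T_)
  bounds[n_epochs] <- T_
  starts <- c(1L, head(bounds, -1) + 1L)
  if (any(starts > bounds)) stop("empty epoch", call. = FALSE)
  fm <- t(vapply(seq_len(n_epochs), function(e) {
    lab <- seq[starts[e]:bounds[e]]
    tabulate(lab[lab > 0], nbins = 36) / length(lab)
  }, numeric(36)))
  structure(fm, class = c("pd_features", "matrix"),
            epoch_sizes = bounds - starts + 1L, empty = all(seq == 0))
}

# random row-stochastic matrix
rand_stoch <- function(nr, nc) {
  m <- matrix(stats::rgamma(nr * nc, 1), nr, nc)
  m / rowSums(m)
}

#' Fit a discrete hidden Markov model to a DoCM label sequence
#'
#' Baum-Welch (EM) over the 37-symbol alphabet {0, ..., 36}, run to
#' convergence (default tolerance 1e-4 on the log-likelihood, 200 iterations)
#' from several random restarts per candidate state count; the state count is
#' selected by BIC. The per-iteration log-likelihood trace of EM is monotone
#' non-decreasing. For classification, a lightly smoothed emission matrix
#' (mixture with uniform, weight `smooth`) is stored so unseen symbols keep
#' finite log-likelihood.
#'
#' @param seq Integer label sequence (0..36).
#' @param state_grid Candidate numbers of hidden states (default 2:3).
#' @param n_restarts Random EM restarts per state count (default 2).
#' @param tol Convergence tolerance on the log-likelihood.
#' @param max_iter Maximum EM iterations.
#' @param n_symbols Alphabet size (default 37).
#' @param smooth Uniform-mixture weight for the stored emission matrix.
#' @param seed Optional seed.
#' @return A `dhmm` object: list with `prior`, `trans`, `emis` (smoothed),
#'   `emis_raw`, `n_states`, `loglik`, `bic`, `ll_trace`, `n_symbols`.
#' @export
fit_dhmm <- function(seq, state_grid = 2:3, n_restarts = 2, tol = 1e-4,
                     max_iter = 200, n_symbols = 37, smooth = 1e-3,
                     seed = NULL) {
  seq <- as.integer(seq)
  if (any(seq < 0 | seq >= n_symbols)) stop("symbol outside alphabet", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  T_ <- length(seq)
  if (length(unique(seq)) == 1) {
    warning("degenerate single-symbol sequence: returning a 1-state model",
            call. = FALSE)
    emis_raw <- matrix(smooth / n_symbols, 1, n_symbols)
    emis_raw[1, seq[1] + 1] <- 1
    emis_raw <- emis_raw / sum(emis_raw)
    return(structure(list(prior = 1, trans = matrix(1, 1, 1),
                          emis = emis_raw, emis_raw = emis_raw,
                          n_states = 1L, loglik = T_ * log(max(emis_raw)),
                          bic = NA_real_, ll_trace = numeric(0),
                          n_symbols = n_symbols), class = "dhmm"))
  }
  if (T_ < 10 * max(state_grid)) {
    stop("sequence too short for the largest candidate state count", call. = FALSE)
  }
  best <- NULL
  for (K in state_grid) {
    fit_k <- NULL
    for (r in seq_len(n_restarts)) {
      prior0 <- as.numeric(rand_stoch(1, K))
      trans0 <- rand_stoch(K, K) + diag(K)  # sticky-ish start
      trans0 <- trans0 / rowSums(trans0)
      emis0 <- rand_stoch(K, n_symbols) + 1e-3
      emis0 <- emis0 / rowSums(emis0)
      fit <- hmm_baum_welch_cpp(seq, K, n_symbols, prior0, trans0, emis0,
                                tol, max_iter)
      if (is.null(fit_k) || fit$loglik > fit_k$loglik) fit_k <- fit
    }
    n_par <- (K - 1) + K * (K - 1) + K * (n_symbols - 1)
    bic <- -2 * fit_k$loglik + n_par * log(T_)
    if (is.null(best) || bic < best$bic) {
      best <- list(fit = fit_k, bic = bic, K = K)
    }
  }
  emis_raw <- best$fit$emis
  emis <- (1 - smooth) * emis_raw + smooth / n_symbols
  structure(list(prior = as.numeric(best$fit$prior), trans = best$fit$trans,
                 emis = emis, emis_raw = emis_raw,
                 n_states = as.integer(best$K), loglik = best$fit$loglik,
                 bic = best$bic, ll_trace = as.numeric(best$fit$ll_trace),
                 n_symbols = n_symbols), class = "dhmm")
}

#' @export
print.dhmm <- function(x, ...) {
  cat(sprintf("<dhmm> %d states over %d symbols, loglik %.2f (BIC %.1f)\n",
              x$n_states, x$n_symbols, x$loglik, x$bic))
  invisible(x)
}

#' Forward-algorithm log-likelihood of a label sequence under a dHMM
#'
#' Scaled forward recursion (no underflow for sequences up to 1e5 windows).
#' The empty sequence scores 0 (empty-product convention).
#'
#' @param model A `dhmm` object.
#' @param seq Integer label sequence (0..36).
#' @param smoothed Use the smoothed emission matrix (default TRUE; keeps
#'   cross-subject scores finite when a test sequence contains symbols unseen
#'   in training).
#' @return Log-likelihood (scalar).
#' @export
dhmm_loglik <- function(model, seq, smoothed = TRUE) {
  stopifnot(inherits(model, "dhmm"))
  seq <- as.integer(seq)
  if (length(seq) == 0) return(0)
  if (any(seq < 0 | seq >= model$n_symbols)) {
    stop("symbol outside the model alphabet", call. = FALSE)
  }
  em <- if (smoothed) model$emis else model$emis_raw
  hmm_forward_cpp(seq, model$prior,
                  matrix(model$trans, model$n_states), matrix(em, model$n_states))
}

#' @export
logLik.dhmm <- function(object, seq, ...) {
  val <- dhmm_loglik(object, seq)
  structure(val, df = (object$n_states - 1) +
              object$n_states * (object$n_states - 1) +
              object$n_states * (object$n_symbols - 1),
            class = "logLik")
}

#' @export
tidy.dhmm <- function(x, ...) {
  K <- x$n_states
  dplyr::bind_rows(
    tibble(matrix = "prior", from = seq_len(K), to = NA_integer_,
           value = as.numeric(x$prior)),
    tibble(matrix = "transition", from = rep(seq_len(K), K),
           to = rep(seq_len(K), each = K), value = as.numeric(x$trans)),
    tibble(matrix = "emission", from = rep(seq_len(K), x$n_symbols),
           to = rep(0:(x$n_symbols - 1), each = K), value = as.numeric(x$emis))
  )
}

#' @export
glance.dhmm <- function(x, ...) {
  tibble(n_states = x$n_states, n_symbols = x$n_symbols,
         loglik = x$loglik, bic = x$bic, n_iter = length(x$ll_trace))
}

#' Simulate a label sequence from a dHMM (for tests and power checks)
#'
#' @param model A `dhmm` or a list with `prior`, `trans`, `emis`.
#' @param n Sequence length.
#' @return Integer vector of symbols 0..(n_symbols-1).
#' @export
simulate_dhmm <- function(model, n) {
  K <- length(model$prior)
  S <- ncol(model$emis)
  s <- integer(n); y <- integer(n)
  s[1] <- sample(K, 1, prob = model$prior)
  y[1] <- sample(S, 1, prob = model$emis[s[1], ]) - 1L
  for (t in seq_len(n)[-1]) {
    s[t] <- sample(K, 1, prob = model$trans[s[t - 1], ])
    y[t] <- sample(S, 1, prob = model$emis[s[t], ]) - 1L
  }
  y
}
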