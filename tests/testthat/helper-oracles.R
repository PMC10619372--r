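# Independent reference implementations used as oracles. These deliberately
# avoid the package's internal helpers: phases come from an explicitly coded
# DFT Hilbert transform and the imaginary part is taken as a mean of sines.

oracle_analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  m <- numeric(n)
  m[1] <- 1
  if (n %% 2 == 0) {
    m[n / 2 + 1] <- 1
    m[2:(n / 2)] <- 2
  } else {
    m[2:((n + 1) / 2)] <- 2
  }
  a <- stats::fft(X * m, inverse = TRUE) / n
  atan2(Im(a), Re(a))
}

oracle_filt <- function(x, lo, hi, rate) {
  bf <- signal::butter(3, c(lo, hi) / (rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

oracle_iplv <- function(x, y, lo, hi, rate) {
  px <- oracle_analytic_phase(oracle_filt(x, lo, hi, rate))
  py <- oracle_analytic_phase(oracle_filt(y, lo, hi, rate))
  abs(mean(sin(px - py)))
}

oracle_pac <- function(x, y, lo1, hi1, lo2, hi2, rate) {
  px <- oracle_analytic_phase(oracle_filt(x, lo1, hi1, rate))
  yh <- oracle_filt(y, lo2, hi2, rate)
  a <- stats::fft(yh)
  n <- length(yh)
  m <- numeric(n)
  m[1] <- 1
  if (n %% 2 == 0) { m[n / 2 + 1] <- 1; m[2:(n / 2)] <- 2 } else m[2:((n + 1) / 2)] <- 2
  env <- Mod(stats::fft(a * m, inverse = TRUE) / n)
  pe <- oracle_analytic_phase(oracle_filt(env, lo1, hi1, rate))
  abs(mean(sin(px - pe)))
}

# exhaustive all-paths forward likelihood (tiny instances only)
oracle_forward_loglik <- function(obs, prior, trans, emis) {
  K <- length(prior)
  T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    p <- prior[paths[r, 1]] * emis[paths[r, 1], obs[1] + 1]
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p * trans[paths[r, t - 1], paths[r, t]] * emis[paths[r, t], obs[t] + 1]
      }
    }
    tot <- tot + p
  }
  log(tot)
}

# label sequences drawn from per-subject dHMMs: identity carried by the
# informative edges' emission alphabets, noise edges shared across subjects
make_synthetic_seqs <- function(n_subjects, n_edges, informative, T_ = 400,
                                seed = 1) {
  set.seed(seed)
  noise_mod <- list(prior = 1, trans = matrix(1, 1, 1),
                    emis = matrix(rep(1 / 37, 37), 1))
  subject_models <- lapply(seq_len(n_subjects), function(k) {
    lapply(seq_len(n_edges), function(e) {
      if (e %in% informative) {
        syms <- sample(1:36, 2)
        em <- matrix(1e-4, 2, 37)
        em[1, syms[1] + 1] <- 1; em[2, syms[2] + 1] <- 1
        em <- em / rowSums(em)
        list(prior = c(.5, .5),
             trans = matrix(c(.9, .1, .1, .9), 2, byrow = TRUE), emis = em)
      } else noise_mod
    })
  })
  draw <- function() {
    lapply(seq_len(n_subjects), function(k) {
      vapply(seq_len(n_edges), function(e) {
        simulate_dhmm(subject_models[[k]][[e]], T_)
      }, integer(T_))
    })
  }
  list(s1 = draw(), s2 = draw())
}
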