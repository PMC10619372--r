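test_that("epoch feature matrix reproduces the full-scale epoch split", {
  fm <- pd_feature_matrix(rep(1L, 2991))
  expect_equal(attr(fm, "epoch_sizes"), c(500L, 500L, 500L, 500L, 500L, 491L))
  expect_equal(dim(fm), c(6, 36))
  fm5 <- pd_feature_matrix(rep(5L, 600))
  expect_true(all(fm5[, 5] == 1))
  expect_true(all(fm5[, -5] == 0))
  fm0 <- pd_feature_matrix(rep(0L, 60))
  expect_true(all(fm0 == 0))
  expect_true(attr(fm0, "empty"))
  # zero labels count in the denominator: rows sum to <= 1
  fmz <- pd_feature_matrix(rep(c(0L, 5L), 30))
  expect_true(all(abs(rowSums(fmz) - 0.5) < 1e-12))
  expect_error(pd_feature_matrix(1:3), "shorter")
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(1)
  for (r in 1:10) {
    prior <- as.numeric(docm:::rand_stoch(1, 2))
    trans <- docm:::rand_stoch(2, 2)
    emis <- docm:::rand_stoch(2, 5)
    obs <- sample(0:4, 6, replace = TRUE)
    got <- docm:::hmm_forward_cpp(obs, prior, trans, emis)
    want <- oracle_forward_loglik(obs, prior, trans, emis)
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("Baum-Welch log-likelihood trace is monotone non-decreasing", {
  set.seed(2)
  y <- sample(0:6, 500, replace = TRUE)
  fit <- fit_dhmm(y, state_grid = 3, n_symbols = 7, seed = 3)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("BIC recovers the true state count of a well-separated 2-state chain", {
  set.seed(4)
  truth <- list(prior = c(0.5, 0.5),
                trans = matrix(c(0.9, 0.1, 0.15, 0.85), 2, byrow = TRUE),
                emis = local({
                  e <- matrix(1e-3 / 35, 2, 37)
                  e[1, 3] <- 1; e[2, 21] <- 1
                  e / rowSums(e)
                }))
  hits <- vapply(1:25, function(s) {
    y <- simulate_dhmm(truth, 1500)
    fit_dhmm(y, state_grid = 2:3, n_restarts = 1, max_iter = 100,
             seed = s)$n_states == 2L
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("fitted transition matrices recover the truth in total variation", {
  set.seed(5)
  truth <- list(prior = c(0.5, 0.5),
                trans = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
                emis = local({
                  e <- matrix(1e-4, 2, 37)
                  e[1, 4] <- 1; e[2, 30] <- 1
                  e / rowSums(e)
                }))
  y <- simulate_dhmm(truth, 3000)
  fit <- fit_dhmm(y, state_grid = 2, seed = 6)
  # align states by emission argmax
  ord <- order(apply(fit$emis_raw, 1, which.max) != 4)
  tr <- fit$trans[ord, ord]
  tv <- max(rowSums(abs(tr - truth$trans)) / 2)
  expect_lt(tv, 0.1)
})

test_that("degenerate, constant and empty sequences are handled", {
  expect_warning(fit <- fit_dhmm(rep(7L, 60)), "degenerate")
  expect_equal(fit$n_states, 1L)
  expect_gte(fit$emis[1, 8], 0.99)
  expect_equal(dhmm_loglik(fit, integer(0)), 0)
  expect_error(dhmm_loglik(fit, c(1L, 40L)), "alphabet")
  expect_error(fit_dhmm(c(1L, 2L), state_grid = 2), "too short")
})

test_that("sequences score higher under their own model than under another subject's", {
  set.seed(7)
  wins <- vapply(1:12, function(r) {
    m1 <- list(prior = c(.5, .5), trans = matrix(c(.9, .1, .1, .9), 2),
               emis = local({e <- matrix(1e-4, 2, 37); e[1, 3] <- 1; e[2, 12] <- 1
                             e / rowSums(e)}))
    m2 <- list(prior = c(.5, .5), trans = matrix(c(.8, .2, .2, .8), 2),
               emis = local({e <- matrix(1e-4, 2, 37); e[1, 7] <- 1; e[2, 25] <- 1
                             e / rowSums(e)}))
    y1 <- simulate_dhmm(m1, 400); y2 <- simulate_dhmm(m2, 400)
    f1 <- fit_dhmm(y1, state_grid = 2, n_restarts = 1, max_iter = 100, seed = r)
    f2 <- fit_dhmm(y2, state_grid = 2, n_restarts = 1, max_iter = 100,
                   seed = r + 1000)
    y1b <- simulate_dhmm(m1, 400)
    dhmm_loglik(f1, y1b) > dhmm_loglik(f2, y1b)
  }, TRUE)
  expect_gt(mean(wins), 0.9)
})
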