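rate <- 600

test_that("a 5-minute component at 2-s non-overlapping windows yields 150 windows", {
  set.seed(1)
  rep <- screen_components(matrix(rnorm(300 * rate), ncol = 1), rate)
  expect_equal(rep$n_windows, 150)
})

test_that("stationary Gaussian components are rarely flagged", {
  set.seed(2)
  comps <- matrix(rnorm(60 * rate * 30), ncol = 30)
  rep <- screen_components(comps, rate)
  expect_lt(mean(rep$artifact), 0.05)
  # per-window false-flag rate (all three metrics outside +/-2 z) is small
  expect_lt(sum(rep$n_flagged) / sum(rep$n_windows), 0.05)
})

test_that("burst-contaminated and constant components are flagged", {
  set.seed(3)
  n <- 60 * rate
  x <- rnorm(n)
  win_n <- 2 * rate
  nw <- n %/% win_n
  bad <- sample(nw, round(0.4 * nw))
  for (w in bad) {
    idx <- ((w - 1) * win_n + 1):(w * win_n)
    # one-sided heavy-tailed spike bursts: kurtosis and skewness explode,
    # the Renyi entropy collapses
    amp <- 30 * exp(rnorm(1, 0, 1.5))
    k <- sample(win_n, 8)
    x[idx[k]] <- x[idx[k]] + amp
  }
  rep <- screen_components(cbind(x, rnorm(n)), rate)
  expect_true(rep$artifact[1])
  expect_false(rep$artifact[2])
  repc <- screen_components(cbind(rep(1, 2 * win_n)), rate)
  expect_true(repc$artifact[1])
  expect_equal(repc$reason[1], "degenerate")
})

test_that("ROI representative weights follow the connectivity-strength rule", {
  set.seed(4)
  n <- 4000
  # brute-force oracle for the weight chain
  oracle_weights <- function(v) {
    k <- nrow(v)
    ss <- numeric(k)
    for (a in seq_len(k)) {
      for (b in seq_len(k)) {
        if (a != b) ss[a] <- ss[a] + abs(cor(v[a, ], v[b, ]))
      }
    }
    ss / sum(ss)
  }
  base <- rnorm(n)
  v <- rbind(base + 0.2 * rnorm(n),
             base + 0.25 * rnorm(n),
             base + 0.3 * rnorm(n),
             rnorm(n))
  r <- roi_representative(v)
  expect_lt(abs(sum(r$weights) - 1), 1e-12)
  expect_equal(r$weights, oracle_weights(v), tolerance = 1e-12)
  expect_equal(which.min(r$weights), 4)  # the independent-noise voxel
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  r2 <- roi_representative(v[perm, ])
  expect_equal(r2$weights, r$weights[perm], tolerance = 1e-12)
  expect_equal(r2$representative, r$representative, tolerance = 1e-10)
})

test_that("ROI representative handles identical voxels, singletons and NaN", {
  x <- rnorm(500)
  r <- roi_representative(rbind(x, x))
  expect_equal(r$weights, c(0.5, 0.5))
  expect_equal(r$representative, x)
  r1 <- roi_representative(rbind(x))
  expect_equal(r1$weights, 1)
  expect_equal(r1$representative, x)
  bad <- rbind(x, x); bad[2, 3] <- NaN
  expect_error(roi_representative(bad), "NaN")
})
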