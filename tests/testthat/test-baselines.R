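rate <- 600
bands <- canonical_bands()

test_that("PSD profiles localize tones and concatenate per ROI", {
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  x <- cbind(sin(2 * pi * 10 * t) + 0.1 * rnorm(length(t)),
             sin(2 * pi * 25 * t) + 0.1 * rnorm(length(t)))
  prof <- psd_profile(x, rate)
  expect_length(prof, 2 * 181)
  roi1 <- prof[1:181]
  freq <- (0:180) * 0.5
  expect_equal(freq[which.max(roi1)], 10)
  alpha_prof <- psd_profile(x, rate, band = bands$alpha1)
  expect_length(alpha_prof, 2 * sum(freq >= 8 & freq <= 10))
  expect_error(psd_profile(x, rate = 100), "180")
})

test_that("correlation matching is exact on identical or shuffled profiles", {
  set.seed(1)
  p1 <- matrix(rnorm(6 * 50), 6)
  cm <- correlation_match(p1, p1)
  expect_equal(cm$accuracy, 1)
  perm <- c(4, 1, 2, 6, 3, 5)
  cm2 <- correlation_match(p1, p1[perm, ], truth = order(perm))
  expect_equal(cm2$accuracy, 1)  # every profile found at its shuffled position
  expect_equal(order(perm), cm2$assignment)
  expect_error(correlation_match(p1, p1[, 1:10]), "dimensions")
  expect_error(correlation_match(rbind(rep(1, 50), rnorm(50)), p1[1:2, ]),
               "zero-variance")
})

test_that("independent random profiles match at chance", {
  set.seed(2)
  acc <- vapply(1:50, function(r) {
    correlation_match(matrix(rnorm(40 * 30), 40),
                      matrix(rnorm(40 * 30), 40))$accuracy
  }, 0)
  expect_equal(mean(acc), 1 / 40, tolerance = 0.5)
})

test_that("static connectome profiles have length R*(R-1)/2", {
  set.seed(3)
  x <- matrix(rnorm(2 * rate * 10), ncol = 10)
  prof <- static_fc_profile(x, rate, bands$alpha2)
  expect_length(prof, 45)
  expect_true(all(prof >= 0 & prof <= 1))
  expect_equal(90 * 89 / 2, 4005)
})

test_that("static iPLV of a stationary coupled pair matches the windowed mean", {
  set.seed(4)
  x <- gen_oscillatory_source(bands$alpha2, 30, rate)
  y <- plant_phase_coupling(x, bands$alpha2, rate, lag = pi / 2, strength = 0.9)
  stat <- iplv(x, y, bands$alpha2, rate)
  px <- instantaneous_phase(x, bands$alpha2, rate)
  py <- instantaneous_phase(y, bands$alpha2, rate)
  wins <- sliding_windows(30, rate = rate)
  wvals <- docm:::windowed_iplv_cpp(px, py, wins$start, attr(wins, "width_samples"))
  expect_equal(stat, mean(wvals), tolerance = 0.05)
})

test_that("dynamic-strength matching is exact on copied sessions", {
  set.seed(5)
  s1 <- lapply(1:4, function(i) matrix(runif(50 * 6), 50))
  dm <- dynamic_strength_match(s1, s1)
  expect_equal(dm$accuracy, 1)
  expect_equal(dm$assignment, 1:4)
  s2 <- lapply(1:4, function(i) matrix(runif(40 * 6), 40))
  expect_error(dynamic_strength_match(s1, s2), "shape")
})

test_that("random-subset control is reproducible and degenerates at full k", {
  set.seed(6)
  sim <- make_synthetic_seqs(4, 6, informative = 1:2, T_ = 200, seed = 8)
  models <- fit_edge_models(sim$s1, state_grid = 2, seed = 9)
  cube <- edge_loglik_cube(models, sim$s2)
  r1 <- random_subset_control(cube, k = 2, n_draws = 50, seed = 3)
  r2 <- random_subset_control(cube, k = 2, n_draws = 50, seed = 3)
  expect_identical(r1$accuracies, r2$accuracies)
  rf <- random_subset_control(cube, k = 6, n_draws = 10, seed = 4)
  expect_equal(rf$sd, 0)
  expect_error(random_subset_control(cube, k = 7), "exceeds")
})
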