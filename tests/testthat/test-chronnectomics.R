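test_that("comodulogram tabulates mode probabilities in the 8x8 layout", {
  cm <- comodulogram(c(3, 3, 3, 3))
  expect_equal(cm[3, 3], 1)
  expect_equal(sum(cm), 1)
  cm2 <- comodulogram(c(1, 9, 1, 9))
  expect_equal(cm2[1, 1], 0.5)   # delta-delta
  expect_equal(cm2[1, 2], 0.5)   # delta->theta
  expect_equal(sum(cm2), 1)
  cm0 <- comodulogram(c(0, 0, 0))
  expect_true(all(cm0 == 0))
  expect_true(attr(cm0, "empty"))
  # zero labels are excluded from the denominator, not treated as a mode
  cm3 <- comodulogram(c(0, 0, 5, 5))
  expect_equal(sum(cm3), 1)
  expect_error(comodulogram(c(1, 37)), "0..36")
})

test_that("flexibility index counts consecutive-mode changes", {
  fi <- flexibility_index(array(c(1, 1, 2, 2, 3), c(5, 1, 1)))
  expect_equal(fi$fi[1, 1], 0.5)
  expect_equal(flexibility_index(array(7, c(10, 1, 1)))$fi[1, 1], 0)
  expect_equal(flexibility_index(array(rep(c(1, 2), 5), c(10, 1, 1)))$fi[1, 1], 1)
  expect_error(flexibility_index(array(1, c(1, 2, 2))), "2 windows")
})

test_that("global FI equals the brute-force mean over enumerated pairs", {
  set.seed(1)
  R <- 5; T_ <- 40
  labels <- array(sample(0:4, T_ * R * R, TRUE), c(T_, R, R))
  for (i in 1:R) for (j in 1:R) labels[, j, i] <- labels[, i, j]
  fi <- flexibility_index(labels)
  brute <- c()
  for (i in 1:(R - 1)) {
    for (j in (i + 1):R) {
      brute <- c(brute, mean(labels[-1, i, j] != labels[-T_, i, j]))
    }
  }
  expect_equal(fi$fi_global, mean(brute))
  expect_true(all(fi$fi >= 0 & fi$fi <= 1))
})

test_that("FI is invariant under relabelling bijections of nonzero modes", {
  set.seed(2)
  labels <- array(sample(c(0L, 3L, 17L, 30L), 200, TRUE), c(50, 2, 2))
  remap <- c(3L, 17L, 30L)
  relab <- labels
  relab[labels == 3L] <- 17L
  relab[labels == 17L] <- 30L
  relab[labels == 30L] <- 3L
  expect_equal(flexibility_index(labels)$fi, flexibility_index(relab)$fi)
})

test_that("default window-optimization grids span the 11 x 10 search space", {
  f <- formals(optimize_window_params)
  widths <- eval(f$widths)
  steps <- eval(f$steps)
  expect_length(widths, 11)
  expect_length(steps, 10)
  expect_equal(length(widths) * length(steps), 110)
  expect_equal(range(widths), c(0.5, 3))
  expect_equal(range(steps), c(0.05, 0.5))
})

test_that("identical sessions give repeatability 1 at every grid point", {
  set.seed(3)
  cohort <- gen_cohort(3, n_rois = 4, duration = 12, n_driven = 2, seed = 5)
  for (s in seq_along(cohort$subjects)) {
    cohort$subjects[[s]]$sessions[[2]] <- cohort$subjects[[s]]$sessions[[1]]
  }
  opt <- suppressWarnings(
    optimize_window_params(cohort, widths = 1, steps = c(0.25, 0.5)))
  expect_true(all(opt$surface$repeatability == 1))
  expect_error(
    optimize_window_params(cohort, widths = 99, steps = 0.1), "exceeds")
})
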