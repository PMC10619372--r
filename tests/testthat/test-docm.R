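full_cfg <- suppressWarnings(surrogate_config_fullscale())

test_that("dominant-mode selection applies the three survivor conditions", {
  # 1e-4 does not beat 0.001/36: no survivor
  p <- rep(1, 36); p[3] <- 1e-4
  s <- rep(0.5, 36)
  expect_equal(select_dominant(p, s, full_cfg)$label, 0L)
  # two survivors: the stronger wins
  p2 <- rep(1, 36); p2[c(3, 17)] <- 1e-6
  s2 <- rep(0, 36); s2[3] <- 0.4; s2[17] <- 0.6
  got <- select_dominant(p2, s2, full_cfg)
  expect_equal(got$label, 17L)
  expect_equal(got$strength, 0.6)
  # none significant
  expect_equal(select_dominant(rep(1, 36), s, full_cfg)$label, 0L)
  # tie on strength -> lower p, then lower mode index
  p3 <- rep(1, 36); p3[c(5, 9)] <- c(1e-6, 1e-8)
  s3 <- rep(0, 36); s3[c(5, 9)] <- 0.5
  expect_equal(select_dominant(p3, s3, full_cfg)$label, 9L)
  expect_error(select_dominant(c(NA, rep(1, 35)), s, full_cfg), "NaN")
})

test_that("orientation resolution prefers the lower p, then the higher strength", {
  e1 <- list(label = 14L, strength = 0.5, p = 0.001)
  e2 <- list(label = 1L, strength = 0.7, p = 0.002)
  expect_equal(resolve_symmetry(e1, e2)$label, 14L)
  e2$p <- 0.001
  expect_equal(resolve_symmetry(e1, e2)$label, 1L)  # tie -> strength 0.7 wins
  z <- list(label = 0L, strength = 0, p = 1)
  expect_equal(resolve_symmetry(z, z)$label, 0L)
})

test_that("per-window BH filter reproduces hand-computed thresholds", {
  expect_false(any(fdr_filter(matrix(1, 3, 10), q = 0.01)))
  p <- matrix(c(rep(1e-4, 3), rep(0.5, 7)), 1)
  mask <- fdr_filter(p, q = 0.01)
  expect_equal(sum(mask), 3)
  expect_true(all(mask[1, 1:3]))
  # null calibration: mean false-discovery proportion stays at or below q
  set.seed(1)
  fdp <- vapply(1:500, function(r) {
    m <- fdr_filter(matrix(runif(40), 1), q = 0.05)
    sum(m) / max(1, sum(m))
  }, 0)
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 / 500))
})

test_that("planted couplings dominate the iDFCG and null edges stay empty", {
  set.seed(42)
  plan <- coupling_plan(4, rbind(c(1, 2), c(3, 4)),
                        list(3L, mode_index(2L, 8L)),
                        list(matrix(1, 1, 1), matrix(1, 1, 1)),
                        strength = 1, depth = 0.9)
  subj <- gen_subject(plan, 30, 600, seed = 7, n_sessions = 1)
  idf <- build_idfcg(suppressWarnings(compute_dfcg(subj$sessions[[1]], 600)))
  s12 <- docm_sequence(idf, 1, 2)
  s34 <- docm_sequence(idf, 3, 4)
  modal <- function(v) as.integer(names(which.max(table(v[v > 0]))))
  expect_equal(modal(s12), 3L)
  expect_equal(modal(s34), mode_index(2L, 8L))
  # labels and strengths vanish together
  expect_true(all((idf$labels == 0) == (idf$strengths == 0)))
  # symmetric outputs
  expect_equal(idf$labels, aperm(idf$labels, c(1, 3, 2)))
})

test_that("a pure-noise network keeps nearly all pair-windows unlabelled", {
  set.seed(9)
  x <- vapply(1:4, function(i) rnorm(30 * 600), numeric(30 * 600))
  idf <- build_idfcg(suppressWarnings(compute_dfcg(x, 600)))
  cfg <- surrogate_config()
  expect_lte(nonzero_fraction(idf), 2 * cfg$fdr_q + 0.05)
})

test_that("detection of a planted mode is monotone in coupling strength", {
  set.seed(11)
  rates <- vapply(c(0, 0.5, 1), function(s) {
    plan <- coupling_plan(2, rbind(c(1, 2)), list(4L),
                          list(matrix(1, 1, 1)), strength = s)
    subj <- gen_subject(plan, 30, 600, seed = 3, n_sessions = 1)
    idf <- build_idfcg(suppressWarnings(compute_dfcg(subj$sessions[[1]], 600)))
    mean(docm_sequence(idf, 1, 2) == 4L)
  }, 0)
  expect_true(all(diff(rates) > -0.02))
  expect_gt(rates[3], rates[1])
})
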