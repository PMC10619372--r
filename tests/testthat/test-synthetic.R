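bands <- canonical_bands()
rate <- 600

test_that("oscillatory sources are band-limited, unit-variance and deterministic", {
  x <- gen_oscillatory_source(bands$alpha1, 30, rate, seed = 1)
  expect_equal(sd(x), 1)
  w <- welch_psd(x, rate)
  expect_true(w$freq[which.max(w$power)] >= 8 && w$freq[which.max(w$power)] <= 10)
  inband <- w$freq >= 8 - 1 & w$freq <= 10 + 1
  expect_gt(sum(w$power[inband]) / sum(w$power), 0.9)
  expect_identical(x, gen_oscillatory_source(bands$alpha1, 30, rate, seed = 1))
  expect_error(gen_oscillatory_source(bands$alpha1, 0, rate), "empty")
  expect_error(gen_oscillatory_source(bands$gamma2, 30, rate = 100), "twice")
})

test_that("planted phase coupling follows the strength/lag contract", {
  set.seed(2)
  x <- gen_oscillatory_source(bands$alpha1, 30, rate)
  y <- plant_phase_coupling(x, bands$alpha1, rate, lag = pi / 2, strength = 1)
  expect_gt(iplv(x, y, bands$alpha1, rate), 0.95)
  expect_warning(y0 <- plant_phase_coupling(x, bands$alpha1, rate, lag = 0,
                                            strength = 1), "zero-lag")
  expect_lt(iplv(x, y0, bands$alpha1, rate), 0.05)
  expect_error(plant_phase_coupling(x, bands$alpha1, rate, strength = 1.2),
               "strength")
})

test_that("zero-strength planting matches the independent-pair null", {
  set.seed(3)
  vals0 <- vapply(1:30, function(r) {
    x <- gen_oscillatory_source(bands$alpha2, 5, rate)
    iplv(x, plant_phase_coupling(x, bands$alpha2, rate, strength = 0),
         bands$alpha2, rate)
  }, 0)
  null <- vapply(1:30, function(r) {
    iplv(gen_oscillatory_source(bands$alpha2, 5, rate),
         gen_oscillatory_source(bands$alpha2, 5, rate), bands$alpha2, rate)
  }, 0)
  expect_gt(stats::ks.test(vals0, null)$p.value, 0.01)
})

test_that("planted PAC is detected by the surrogate test and off when depth is 0", {
  set.seed(4)
  width <- 6 * rate  # 6-s analysis window inside a 30-s recording
  x <- gen_oscillatory_source(bands$theta, 30, rate)
  y <- plant_pac(x, bands$theta, bands$gamma2, rate, depth = 0.9)
  px <- instantaneous_phase(x, bands$theta, rate)
  pe <- docm:::envelope_phase(y, bands$theta, bands$gamma2, rate)
  obs <- abs(Im(mean(exp(1i * (px[1:width] - pe[1:width])))))
  null <- docm:::rotation_null_cpp(px, pe, 1L, width, 2000, 0.02, FALSE)
  expect_lt(surrogate_pvalue(obs, null), 0.001)
  # depth 0: surrogate p spread over (0, 1), not stacked at the low end
  p0 <- vapply(1:25, function(r) {
    x0 <- gen_oscillatory_source(bands$theta, 18, rate)
    y0 <- plant_pac(x0, bands$theta, bands$gamma2, rate, depth = 0)
    px0 <- instantaneous_phase(x0, bands$theta, rate)
    pe0 <- docm:::envelope_phase(y0, bands$theta, bands$gamma2, rate)
    surrogate_pvalue(abs(Im(mean(exp(1i * (px0[1:width] - pe0[1:width]))))),
                     docm:::rotation_null_cpp(px0, pe0, 1L, width, 200, 0.02, FALSE))
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(p0, "punif"))$p.value, 0.01)
  expect_error(plant_pac(x, bands$theta, bands$theta, rate), "strictly below")
  expect_error(plant_pac(x, bands$theta, bands$gamma2, rate, depth = 2), "depth")
})

test_that("voxel expansions reconstruct their ROI signal", {
  set.seed(5)
  roi <- gen_oscillatory_source(bands$beta1, 10, rate)
  v <- gen_voxel_rois(roi, 4, noise = 0)
  r <- roi_representative(v)
  expect_gt(cor(r$representative, roi), 0.999999)
  # one dominant voxel gets the largest interpolation weight
  v2 <- gen_voxel_rois(roi, 4, weight_profile = c(0.97, 0.01, 0.01, 0.01),
                       noise = 0.05, seed = 6)
  r2 <- roi_representative(v2)
  expect_equal(which.max(r2$weights), 1)
  v1 <- gen_voxel_rois(roi, 1, noise = 0)
  expect_equal(roi_representative(v1)$representative, roi)
  expect_error(gen_voxel_rois(roi, 3, weight_profile = c(0, 0, 0)), "zero")
})

test_that("cohort generation is deterministic and validates its plan", {
  c1 <- gen_cohort(2, n_rois = 4, duration = 12, n_driven = 2, seed = 3)
  c2 <- gen_cohort(2, n_rois = 4, duration = 12, n_driven = 2, seed = 3)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$edges, c2$edges)
  plan <- c1$plans[[1]]
  expect_error(coupling_plan(2, rbind(c(1, 5)), plan$edge_modes[1],
                             plan$trans[1]), "beyond")
  bad_tm <- list(matrix(c(0.5, 0.2, 0.5, 0.5), 2))
  expect_error(coupling_plan(4, rbind(c(1, 2)), list(c(3L, 9L)), bad_tm),
               "sum to 1")
})

test_that("two-cohort generation records the hidden overlap in the manifest", {
  tc <- gen_two_cohorts(4, 6, n_overlap = 2, seed = 5, n_rois = 4,
                        duration = 12, n_driven = 2)
  expect_equal(nrow(tc$manifest), 2)
  expect_true(all(tc$manifest$cohort1_id %in% 1:4))
  expect_true(all(tc$manifest$cohort2_id %in% 1:6))
  expect_equal(length(tc$cohort2$subjects[[1]]$sessions), 1)
  # overlapping subjects share the cohort-1 plan
  m <- tc$manifest
  for (k in seq_len(nrow(m))) {
    expect_identical(tc$cohort1$plans[[m$cohort1_id[k]]],
                     tc$cohort2$plans[[m$cohort2_id[k]]])
  }
  expect_error(gen_two_cohorts(4, 6, n_overlap = 5), "exceeds")
  expect_error(gen_two_cohorts(-1, 6, 0), "negative")
})

test_that("within-subject comodulograms are more similar than between-subject ones", {
  set.seed(8)
  cohort <- gen_cohort(3, n_rois = 6, duration = 20, n_driven = 3, seed = 21)
  seqs1 <- suppressWarnings(cohort_docm_sequences(cohort, 1))
  seqs2 <- suppressWarnings(cohort_docm_sequences(cohort, 2))
  # comodulogram over the driven edges, flattened
  pr <- attr(seqs1[[1]], "pairs")
  driven_cols <- apply(cohort$edges, 1, function(e) {
    which(pr[, 1] == min(e) & pr[, 2] == max(e))
  })
  cm_of <- function(m) as.numeric(vapply(driven_cols, function(cc) {
    as.numeric(unclass(comodulogram(m[, cc])))
  }, numeric(64)))
  within <- vapply(1:3, function(s) cor(cm_of(seqs1[[s]]), cm_of(seqs2[[s]])), 0)
  between <- c(cor(cm_of(seqs1[[1]]), cm_of(seqs2[[2]])),
               cor(cm_of(seqs1[[2]]), cm_of(seqs2[[3]])),
               cor(cm_of(seqs1[[3]]), cm_of(seqs2[[1]])))
  expect_gt(mean(within), mean(between))
})
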