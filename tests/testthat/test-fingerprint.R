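# synthetic label sequences: identity confined to edges 1-3 of 8
sim <- make_synthetic_seqs(n_subjects = 5, n_edges = 8, informative = 1:3,
                           T_ = 400, seed = 1)
models <- fit_edge_models(sim$s1, state_grid = 2, seed = 2)
cube <- edge_loglik_cube(models, sim$s2)

test_that("informative edges occupy the top ranks", {
  ranked <- rank_edges(cube)
  expect_setequal(ranked$edge[1:3], 1:3)
  expect_true(all(ranked$accuracy[1:3] > 0.8))
  # noise edges sit near chance (1/5)
  expect_lt(mean(ranked$accuracy[ranked$edge > 3]), 0.55)
})

test_that("stepwise aggregation reaches full accuracy with a non-decreasing curve", {
  sel <- stepwise_select(rank_edges(cube), cube)
  expect_equal(sel$accuracy, 1)
  expect_true(all(diff(sel$curve$accuracy) > 0))
  expect_true(all(sel$edges %in% 1:3))
  expect_error(stepwise_select(integer(0), cube), "empty")
})

test_that("the similarity matrix is diagonal-dominant and permutation-consistent", {
  sel <- stepwise_select(rank_edges(cube), cube)
  sim_m <- similarity_matrix(cube, sel$edges)
  expect_true(all(apply(sim_m, 2, which.max) == 1:5))
  # permuting test subjects permutes columns consistently
  perm <- c(3, 1, 5, 2, 4)
  cube_p <- cube[, , perm]
  sim_p <- similarity_matrix(cube_p, sel$edges)
  expect_equal(unclass(sim_p), unclass(sim_m)[, perm])
  # single-edge set equals that edge's loglik matrix
  s1 <- similarity_matrix(cube, 1L)
  expect_equal(unclass(s1), matrix(cube[1, , ], 5, 5))
})

test_that("identity-free cubes classify at chance", {
  sim0 <- make_synthetic_seqs(5, 6, informative = integer(0), T_ = 300, seed = 3)
  models0 <- fit_edge_models(sim0$s1, state_grid = 2, seed = 4)
  cube0 <- edge_loglik_cube(models0, sim0$s2)
  ranked0 <- rank_edges(cube0)
  expect_lt(mean(ranked0$accuracy), 0.5)
  sel0 <- stepwise_select(ranked0, cube0)
  expect_lt(sel0$accuracy, 0.9)
})

test_that("thresholds separate diagonal from off-diagonal score distributions", {
  set.seed(5)
  m <- matrix(rnorm(40 * 40, 570, 15), 40)
  diag(m) <- rnorm(40, 1750, 100)
  dec <- learn_thresholds(structure(m, class = c("similarity_matrix", "matrix")))
  expect_equal(unname(dec$threshold_off["mean"]), 570, tolerance = 0.02)
  expect_equal(unname(dec$threshold_diag["mean"]), 1750, tolerance = 0.02)
  expect_gt(dec$cutoff, 570 + 3 * 16)
  expect_lt(dec$cutoff, 1750 - 3 * 95)
  m22 <- matrix(c(10, 0, 0, 10), 2)
  dec22 <- learn_thresholds(m22)
  expect_equal(dec22$cutoff, 5)
  same <- matrix(5, 3, 3)
  expect_error(learn_thresholds(same), "not separable")
})

test_that("differentiability is the self z-score against cross-subject scores", {
  expect_equal(differentiability(c(1750, 570, 580, 560), self = 1), 118)
  row <- c(600, 600, 610, 590)
  expect_equal(differentiability(row, self = 1), 0)
  expect_error(differentiability(c(1, 1, 1, 1), self = 1), "zero spread")
  expect_error(differentiability(c(1, 2, 3), self = 1), "at least 3")
})

test_that("external matching recovers exactly the overlapping identities", {
  # cohort-2: subjects 2 and 4 of the training cohort reappear (as test
  # subjects 3 and 1), plus three strangers
  set.seed(6)
  strangers <- make_synthetic_seqs(3, 8, informative = 1:3, T_ = 400,
                                   seed = 7)$s1
  cohort2 <- list(sim$s2[[4]], strangers[[1]], sim$s2[[2]], strangers[[2]],
                  strangers[[3]])
  cube2 <- edge_loglik_cube(models, cohort2)
  sel <- stepwise_select(rank_edges(cube), cube)
  dec <- learn_thresholds(similarity_matrix(cube, sel$edges))
  em <- external_match(cube2, sel$edges, dec)
  expect_equal(em$matches$cohort1_id, c(2L, 4L))
  expect_equal(em$matches$cohort2_id, c(3L, 1L))
})

test_that("subnetwork grouping yields 15 runs and surfaces the identity-bearing group", {
  # 7 ROIs over 5 networks; informative edges 1-3 connect ROIs 1-2, 1-3, 2-3
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3), c(1, 4), c(4, 5), c(5, 6),
                 c(6, 7), c(2, 7))
  map5 <- c("A", "A", "A", "B", "C", "D", "E")
  expect_error(subnetwork_performance(cube, pairs, c(map5[-7], NA)), "mapped")
  expect_error(subnetwork_performance(cube, pairs, rep("A", 7)), "5 network")
  perf <- subnetwork_performance(cube, pairs, map5)
  expect_equal(nrow(perf), 15)
  expect_equal(sum(perf$type == "within"), 5)
  expect_equal(sum(perf$type == "between"), 10)
  # pairs 1-3 are (1,2),(1,3),(2,3): all within network A
  best <- perf$group[which.max(perf$accuracy)]
  expect_equal(best, "within-A")
  expect_true(any(is.na(perf$accuracy[perf$n_edges == 0])))
})
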