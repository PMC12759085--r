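test_that("spec validation names the offending field", {
  expect_error(time_series_sim_spec(cluster_sd = 0), "cluster_sd")
  expect_error(time_series_sim_spec(cells_per_cluster = 0),
               "cells_per_cluster")
  bad <- diag(4) * 1.5
  expect_error(time_series_sim_spec(transition_matrix = bad),
               "transition_matrix")
  expect_error(track_sim_spec(n_anchor = 2), "n_anchor")
  expect_error(track_sim_spec(rotation_radius = -1), "rotation_radius")
})

test_that("identity transitions with wide separation give a pure chain truth", {
  sim <- simulate_timepoint_series(time_series_sim_spec(
    n_timepoints = 3, cells_per_cluster = 20,
    transition_matrix = diag(4), seed = 2))
  tr <- sim$truth$edges
  expect_true(all(tr$earlier_cluster == tr$later_cluster))
  expect_true(all(tr$fraction == 1))
})

test_that("true edge fractions equal the transition matrix and the bookkeeping", {
  P <- rbind(c(0.5, 0.3, 0.2, 0.0),
             c(0.0, 0.6, 0.2, 0.2),
             c(0.0, 0.0, 0.8, 0.2),
             c(0.0, 0.0, 0.0, 1.0))
  sim <- simulate_timepoint_series(time_series_sim_spec(
    n_timepoints = 3, cells_per_cluster = 100, transition_matrix = P,
    seed = 4))
  # read back the generator's truth for later cluster C1 at timepoint 2
  e <- sim$truth$edges
  c1 <- e[e$later_cluster == "C1" & e$later_tp == "2", ]
  expect_setequal(c1$fraction, c(0.5, 0.3, 0.2))
  # and verify it independently by counting the assigned parent populations
  book <- sim$assignments
  for (tp in c("2", "3")) for (cl in paste0("C", 1:4)) {
    part <- book[book$timepoint == tp & book$cluster == cl, ]
    counted <- table(factor(part$parent_cluster, paste0("C", 1:4))) /
      nrow(part)
    expect_equal(unname(as.numeric(counted)),
                 P[match(cl, paste0("C", 1:4)), ])
  }
})

test_that("generators are bit-identical under a fixed seed", {
  s1 <- simulate_timepoint_series(time_series_sim_spec(
    n_timepoints = 3, cells_per_cluster = 10, seed = 1))
  s2 <- simulate_timepoint_series(time_series_sim_spec(
    n_timepoints = 3, cells_per_cluster = 10, seed = 1))
  expect_identical(s1, s2)

  t1 <- simulate_explant_tracks(track_sim_spec(seed = 7, n_frames = 20))
  t2 <- simulate_explant_tracks(track_sim_spec(seed = 7, n_frames = 20))
  expect_identical(t1, t2)

  e1 <- simulate_expression_pair(3, 50, 5, 0.3, seed = 5)
  e2 <- simulate_expression_pair(3, 50, 5, 0.3, seed = 5)
  expect_identical(e1, e2)
})

test_that("noiseless tracks decompose by construction", {
  sim <- simulate_explant_tracks(track_sim_spec(
    noise_sd = 0, rotation_radius = 0, n_deep = 4, n_frames = 30,
    seed = 3))
  # with no rotation, every deep track differs from the anchor-centroid
  # trajectory by a constant offset
  et <- as.matrix(sim$et_true[, c("x", "y", "z")])
  for (id in paste0("D", 1:4)) {
    pos <- as.matrix(sim$tracks[[id]]$samples[, c("x", "y", "z")])
    offsets <- pos - et
    expect_lt(max(abs(sweep(offsets, 2, offsets[1, ]))), 1e-9)
  }

  # with rotation, the true migration stays at rotation_radius from its
  # circle center at every frame
  sim2 <- simulate_explant_tracks(track_sim_spec(
    noise_sd = 0, rotation_radius = 8, rotation_period = 10, n_deep = 3,
    n_frames = 30, seed = 9))
  for (mt in sim2$mt_true) {
    pts <- as.matrix(mt[, c("x", "y", "z")])
    fit <- fit_rotation_radius(pts)
    proj <- sweep(pts, 2, colMeans(pts)) %*% fit$basis
    r <- sqrt(rowSums(sweep(proj, 2, fit_circle(proj)$center)^2))
    expect_equal(r, rep(8, nrow(pts)), tolerance = 1e-8)
  }
})

test_that("expression pairs have the stated marker structure", {
  expect_error(simulate_expression_pair(4, 10, 5, 0, seed = 1),
               "marker blocks exceed gene count")

  # noiseless: each query cluster best-matches its true counterpart
  ex <- simulate_expression_pair(4, 60, 5, 0, seed = 1)
  sim <- marker_correlation(aggregate_pseudobulk(ex$query),
                            aggregate_pseudobulk(ex$reference), ex$markers)
  bm <- best_match(sim)
  expect_equal(bm$reference, ex$correspondence$reference)

  # two clusters whose markers tile all genes: profiles are (b+e, b+e, b, b)
  # vs (b, b, b+e, b+e), whose Pearson correlation is exactly -1
  ex2 <- simulate_expression_pair(2, 4, 2, 0, seed = 1)
  sim2 <- marker_correlation(aggregate_pseudobulk(ex2$query),
                             aggregate_pseudobulk(ex2$reference),
                             ex2$markers)
  expect_equal(unname(diag(sim2)), c(1, 1))
  expect_equal(unname(sim2[1, 2]), -1)
  expect_equal(unname(sim2[2, 1]), -1)
})
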