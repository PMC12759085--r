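straight_track <- function(id, n = 10, v = c(1, 0, 0), start = c(0, 0, 0),
                           role = "deep") {
  tt <- 0:(n - 1)
  cell_track(id, tt, start[1] + tt * v[1], start[2] + tt * v[2],
             start[3] + tt * v[3], role = role)
}

test_that("cell_track validates its samples", {
  expect_error(cell_track("t", c(0, 0, 1), 1:3, 1:3, 1:3),
               "strictly increasing")
  expect_error(cell_track("t", 0, 1, 1, 1), "at least 2")
  expect_error(cell_track("t", 0:2, 1:2, 1:3, 1:3), "length")
})

test_that("gap resampling interpolates short gaps and splits long ones", {
  # a 2-frame gap on a straight line: interpolated points fall on it
  tr <- cell_track("g", c(0, 1, 4, 5), c(0, 1, 4, 5), c(0, 2, 8, 10),
                   rep(0, 4))
  out <- resample_gaps(tr, max_gap = 3)
  expect_s3_class(out, "cell_track")
  expect_equal(out$samples$time_index, 0:5)
  expect_equal(out$samples$x, 0:5)
  expect_equal(out$samples$y, seq(0, 10, by = 2))
  expect_equal(out$samples$interpolated, c(F, F, T, T, F, F))

  # a 5-frame gap with max_gap 3 splits the track in two
  tr2 <- cell_track("s", c(0, 1, 7, 8), 1:4, 1:4, 1:4)
  segs <- resample_gaps(tr2, max_gap = 3)
  expect_type(segs, "list")
  expect_length(segs, 2)
  expect_equal(names(segs), c("s.1", "s.2"))
  expect_equal(segs[["s.1"]]$samples$time_index, 0:1)
  expect_equal(segs[["s.2"]]$samples$time_index, 7:8)

  # no gaps: returned unchanged
  tr3 <- straight_track("u", 5)
  expect_identical(resample_gaps(tr3), tr3)
})

test_that("elongation trajectory is the anchor centroid on common support", {
  # static anchors: constant ET
  a <- lapply(1:3, function(i)
    cell_track(paste0("A", i), 0:4, rep(i, 5), rep(0, 5), rep(0, 5),
               role = "anchor"))
  et <- compute_elongation_trajectory(a)
  expect_equal(et$x, rep(2, 5))
  expect_equal(et$y, rep(0, 5))

  # three translating anchors: ET moves at the shared velocity
  b <- lapply(1:3, function(i)
    straight_track(paste0("A", i), 6, v = c(1, 0, 0),
                   start = c(i, i, 0), role = "anchor"))
  et2 <- compute_elongation_trajectory(b)
  expect_equal(diff(et2$x), rep(1, 5))
  expect_equal(diff(et2$y), rep(0, 5))

  # hand centroid of (0,0,0), (2,0,0), (1,3,0)
  starts <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, 0))
  cc <- lapply(1:3, function(i)
    cell_track(paste0("A", i), 0:1, rep(starts[i, 1], 2),
               rep(starts[i, 2], 2), rep(starts[i, 3], 2), role = "anchor"))
  et3 <- compute_elongation_trajectory(cc)
  expect_equal(unlist(et3[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 1, 0))

  expect_error(compute_elongation_trajectory(a[1:2]), "at least 3")
  far <- c(a[1:2], list(cell_track("A3", 50:60, 0:10, 0:10, 0:10,
                                   role = "anchor")))
  expect_error(compute_elongation_trajectory(far), "common time support")
})

test_that("migration trajectory removes exactly the net tissue displacement", {
  anchors <- lapply(1:3, function(i)
    straight_track(paste0("A", i), 8, v = c(2, 1, 0), start = c(i, 0, 0),
                   role = "anchor"))
  et <- compute_elongation_trajectory(anchors)

  # a cell moving with the tissue has a constant migration trajectory
  cell <- straight_track("D1", 8, v = c(2, 1, 0), start = c(5, 5, 5))
  mt <- compute_migration_trajectory(cell, et)
  expect_equal(mt$mt_x, rep(5, 8))
  expect_equal(mt$mt_y, rep(5, 8))
  expect_equal(mt$mt_z, rep(5, 8))

  # constant ET: migration equals the observed trajectory
  static <- lapply(1:3, function(i)
    cell_track(paste0("A", i), 0:7, rep(i, 8), rep(0, 8), rep(0, 8),
               role = "anchor"))
  et0 <- compute_elongation_trajectory(static)
  mt0 <- compute_migration_trajectory(cell, et0)
  expect_equal(mt0$mt_x, mt0$ot_x)
  expect_equal(mt0$mt_y, mt0$ot_y)

  expect_error(compute_migration_trajectory(
    cell_track("D", 100:101, 1:2, 1:2, 1:2), et), "fewer than 2")
})

test_that("decomposition identity holds on noisy synthetic tracks", {
  sim <- simulate_explant_tracks(track_sim_spec(noise_sd = 0.8, n_deep = 8,
                                                n_frames = 40, seed = 21))
  dec <- decompose_tracks(sim$tracks)
  for (d in dec$decompositions) {
    ot <- as.matrix(d[, c("ot_x", "ot_y", "ot_z")])
    et <- as.matrix(d[, c("et_x", "et_y", "et_z")])
    mt <- migration_positions(d)
    det <- sweep(et, 2, et[1, ])
    expect_lt(max(abs(ot - (mt + det))), 1e-9)
  }
})

test_that("circle fit recovers the rotation radius of noiseless deep cells", {
  sim <- simulate_explant_tracks(track_sim_spec(noise_sd = 0, n_deep = 6,
                                                n_frames = 60, seed = 13))
  dec <- decompose_tracks(sim$tracks)
  for (id in paste0("D", 1:6)) {
    r <- fit_rotation_radius(dec$decompositions[[id]])$radius
    expect_equal(r, sim$spec$rotation_radius, tolerance = 0.01)
  }
})

test_that("direction histograms bin projected displacements correctly", {
  # single in-plane displacements land in the sectors containing 0 and 90
  t_e <- cell_track("e", 0:1, c(0, 1), c(0, 0), c(0, 0))
  h_e <- movement_directions(t_e, plane = "xy", bins = 16)
  expect_equal(which(h_e$counts == 1), 1)
  t_n <- cell_track("n", 0:1, c(0, 0), c(0, 1), c(0, 0))
  h_n <- movement_directions(t_n, plane = "xy", bins = 16)
  expect_equal(which(h_n$counts == 1), 5)  # [90, 112.5)

  # 100 random displacements match naive binning, and counts conserve
  set.seed(31)
  steps <- matrix(rnorm(300), ncol = 3)
  pos <- apply(rbind(0, steps), 2, cumsum)
  tr <- cell_track("r", 0:100, pos[, 1], pos[, 2], pos[, 3])
  h <- movement_directions(tr, window = 1, plane = "xy", bins = 16)
  expect_equal(h$counts, oracle_direction_counts(steps[, 1:2], 16))
  expect_equal(sum(h$counts) + h$n_zero, h$n_steps)
  expect_equal(h$n_steps, 100)

  # purely out-of-plane displacement has zero projected length
  t_z <- cell_track("z", 0:1, c(0, 0), c(0, 0), c(0, 1))
  h_z <- movement_directions(t_z, plane = "xy")
  expect_equal(sum(h_z$counts), 0)
  expect_equal(h_z$n_zero, 1)

  # windows longer than one frame and gaps: only complete steps count
  t_g <- cell_track("g", c(0, 2, 4), c(0, 1, 2), c(0, 0, 0), c(0, 0, 0))
  h_g <- movement_directions(t_g, window = 2, plane = "xy")
  expect_equal(h_g$n_steps, 2)

  expect_error(movement_directions(t_e, plane = "bogus"), "plane")
  expect_error(movement_directions(t_e, window = 0), "window")
})

test_that("the default projection plane tracks anchor displacement", {
  anchors <- lapply(1:3, function(i)
    straight_track(paste0("A", i), 10, v = c(0, 0, 1),
                   start = c(i, 2 * i, 0), role = "anchor"))
  jitter_track <- cell_track("D1", 0:9, rnorm(10, sd = .01),
                             rnorm(10, sd = .01), rnorm(10, sd = .01))
  basis <- movement_plane(anchors)
  expect_equal(dim(basis), c(3L, 2L))
  expect_equal(crossprod(basis), diag(2), tolerance = 1e-8,
               ignore_attr = TRUE)
  h <- movement_directions(c(anchors, list(jitter_track)), window = 1)
  # plane resolved from anchors without an explicit spec
  expect_equal(dim(h$plane), c(3L, 2L))
})
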