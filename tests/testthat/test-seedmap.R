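test_that("seed time courses are unweighted means over resolved units", {
  ts <- mk_ts(rbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  one <- seed_region("cortex", units = 1)
  two <- seed_region("cortex", units = c(1, 2))
  expect_equal(seed_timecourse(ts, one), c(1, 2, 3))
  expect_equal(seed_timecourse(ts, two), c(2, 2, 2))
  expect_error(seed_timecourse(ts, seed_region("cortex", units = 9)),
               "bounds")
})

test_that("a 6-mm sphere on the 2-mm grid resolves to the lattice-enumeration count", {
  sc <- build_scene(vertices_per_hemisphere = 50,
                    grid_dim = c(12L, 12L, 12L), seed = 2)
  # pick an in-mask voxel centre at least 6 mm from every mask face
  ctr <- sc$voxel_coords[which(sc$voxel_index[, 1] == 6 &
                                 sc$voxel_index[, 2] == 6 &
                                 sc$voxel_index[, 3] == 6), ]
  run <- simulate_session_set(
    sc, acquisition_plan(n_sessions = 1, runs_per_session = 1,
                         frames_per_run = 10, snr = 0), seed = 3)$runs[[1]]
  rows <- cerebparc:::resolve_seed(
    seed_region("cerebellum_volume", center_mm = ctr, radius_mm = 6),
    run$cerebellum, coords = sc$voxel_coords)
  # independent oracle: integer lattice points with x^2+y^2+z^2 <= 3^2
  grid <- expand.grid(x = -3:3, y = -3:3, z = -3:3)
  oracle <- sum(grid$x^2 + grid$y^2 + grid$z^2 <= 9)
  expect_equal(length(rows), oracle)
  expect_equal(oracle, 123)
})

test_that("correlation maps match direct formula evaluation", {
  seed <- c(1, 2, 3, 4)
  ts <- mk_ts(rbind(seed, c(1, 3, 2, 4), -seed, c(7, 7, 7, 7)))
  m <- correlation_map(ts, seed)
  expect_equal(m$values[1], 1)
  expect_equal(m$values[2], 0.8, tolerance = 1e-12)
  expect_equal(m$values[3], -1)
  expect_equal(m$values[4], 0)        # zero-variance unit: r = 0, flagged
  expect_false(m$mask[4])
  expect_true(all(m$mask[1:3]))
  expect_error(correlation_map(ts, c(1, 2)), "timepoints")
  expect_error(correlation_map(ts, rep(1, 4)), "zero variance")
  # invariance to positive affine rescaling of the seed
  m2 <- correlation_map(ts, 3 * seed + 10)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
})

test_that("fisher_z matches atanh, clamps at |r| = 1 and is odd and monotone", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.9), 0.5 * log(1.9 / 0.1), tolerance = 1e-12)
  expect_equal(fisher_z(0.9), 1.47222, tolerance = 1e-5)
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  expect_true(is.finite(fisher_z(-1)))
  expect_error(fisher_z(1.01), "fisher_z")
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
})

test_that("map averaging is the elementwise mean and commutes with permutation", {
  mk <- function(r) fisher_z(scalar_map(r, "r", unit_space = "cortex"))
  a <- mk(c(0.5, 0.5))
  b <- mk(c(0.5, -0.5))
  avg <- average_maps(list(a, b))
  expect_equal(avg$values, c(atanh(0.5), 0), tolerance = 1e-12)
  expect_equal(average_maps(list(a))$values, a$values)
  expect_equal(average_maps(list(b, a))$values, avg$values)
  expect_equal(average_maps(list(a, a))$values[1], 0.54931,
               tolerance = 1e-5)
  bad <- scalar_map(c(1, 2), "z", unit_space = "cerebellum_volume")
  expect_error(average_maps(list(a, bad)), "unit spaces")
})

test_that("contrasts are antisymmetric and sign-correct on a noiseless subject", {
  a <- scalar_map(c(1, 2, 3), "z")
  b <- scalar_map(c(3, 1, 1), "z")
  expect_equal(contrast_maps(a, b)$values, -contrast_maps(b, a)$values)
  expect_equal(contrast_maps(a, a)$values, c(0, 0, 0))

  # ground-truth sign oracle: left-hand minus right-hand seed map is
  # positive on right-hemisphere hand voxels, negative on left ones
  sc <- tiny_scene
  run <- tiny_noiseless$runs[[1]]
  zmap <- function(hemi) {
    body <- sc[[paste0("cortex_body_", hemi)]]
    v <- which(body == "hand")[1]
    tc <- seed_timecourse(run$cortex,
                          seed_region(paste0("cortex_", hemi), units = v))
    fisher_z(correlation_map(run$cerebellum, tc))
  }
  d <- contrast_maps(zmap("left"), zmap("right"))
  hand <- sc$body_part == "hand"
  right <- sc$hemisphere_of_voxel == "right"
  expect_true(all(d$values[hand & right] > 0))
  expect_true(all(d$values[hand & !right] < 0))
})

test_that("threshold overlays set one bit per map at its own threshold", {
  maps <- list(foot = scalar_map(c(0.15, 0.05, 0.30), "z"),
               hand = scalar_map(c(0.05, 0.25, 0.25), "z"),
               tongue = scalar_map(c(0.00, 0.12, 0.05), "z"))
  thr <- c(foot = 0.1, hand = 0.2, tongue = 0.1)
  ov <- threshold_overlay(maps, thr)
  expect_equal(ov$bits, c(1L, 2L + 4L, 1L + 2L))
  expect_true(ov$members$foot[1])
  expect_true(ov$members$hand[2] && ov$members$tongue[2])
  none <- threshold_overlay(list(foot = scalar_map(c(0.01), "z")),
                            c(foot = 0.1))
  expect_equal(none$bits, 0L)
  expect_error(threshold_overlay(maps, c(foot = 0.1)), "hand")
})
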