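test_that("profiles are vertex-by-ROI Pearson correlations", {
  vt <- mk_ts(rbind(c(1, 2, 3, 4), c(2, 1, 4, 3)))
  prof <- compute_profiles(vt, vt)
  expect_equal(diag(prof$matrix), c(1, 1))
  # hand-computable off-diagonal
  expect_equal(prof$matrix[1, 2], cor(c(1, 2, 3, 4), c(2, 1, 4, 3)),
               tolerance = 1e-12)
  roi <- mk_ts(rbind(c(5, 5, 5, 5), c(1, 2, 3, 4)))
  p2 <- compute_profiles(vt, roi)
  expect_equal(p2$matrix[, 1], c(0, 0))   # constant ROI column: r = 0
  expect_error(compute_profiles(vt, mk_ts(rbind(c(1, 2)))), "timepoints")
})

test_that("top-fraction binarization keeps exactly ceil(fraction * n_roi) per row", {
  row <- c(0.1, 0.9, 0.3, 0.7, 0.2, 0.6, 0.4, 0.5, 0.8, 0.0)
  prof <- conn_profiles(rbind(row, rep(0.5, 10)))
  bin <- binarize_top_fraction(prof, 0.2)
  expect_equal(which(bin$matrix[1, ] == 1), c(2L, 9L))      # 0.9 and 0.8
  expect_equal(which(bin$matrix[2, ] == 1), 1:2)            # tie rule: lowest index
  expect_true(all(rowSums(bin$matrix) == 2))
  # default 10% of 1175 ROIs keeps ceil(117.5) = 118
  wide <- conn_profiles(matrix(runif(1175), 1))
  expect_equal(sum(binarize_top_fraction(wide, 0.10)$matrix), 118)
  expect_error(binarize_top_fraction(prof, 0), "keep_fraction")
  expect_error(binarize_top_fraction(bin, 0.2), "already")
})

test_that("spherical clustering separates planted orthogonal profile groups", {
  set.seed(11)
  a <- c(rep(1, 10), rep(0, 10))
  b <- c(rep(0, 10), rep(1, 10))
  x <- rbind(matrix(rep(a, 30), 30, byrow = TRUE),
             matrix(rep(b, 25), 25, byrow = TRUE))
  planted <- rep(1:2, c(30, 25))
  p <- cluster_profiles(conn_profiles(x, binarized = TRUE), K = 2,
                        restarts = 5, seed = 3)
  m <- match_labels(p, surface_parcellation(planted, 2))
  expect_equal(m$accuracy, 1)
  # duplicating every row leaves the partition of the originals unchanged
  p2 <- cluster_profiles(conn_profiles(rbind(x, x), binarized = TRUE),
                         K = 2, restarts = 5, seed = 3)
  m2 <- match_labels(surface_parcellation(p2$labels[1:55], 2),
                     surface_parcellation(p$labels, 2))
  expect_equal(m2$accuracy, 1)
  # K = 1 labels everything identically
  expect_true(all(cluster_profiles(conn_profiles(x, binarized = TRUE),
                                   K = 1)$labels == 1L))
  expect_error(cluster_profiles(conn_profiles(x[1:4, ] * 0 + 1,
                                              binarized = TRUE), K = 3),
               "distinct")
})

test_that("clustering is invariant to row order up to label matching", {
  set.seed(21)
  base <- diag(4)[rep(1:4, c(12, 9, 7, 5)), ]
  perm <- sample(nrow(base))
  p1 <- cluster_profiles(conn_profiles(base, binarized = TRUE), K = 4,
                         restarts = 10, seed = 5)
  p2 <- cluster_profiles(conn_profiles(base[perm, ], binarized = TRUE),
                         K = 4, restarts = 10, seed = 6)
  unpermuted <- integer(nrow(base))
  unpermuted[perm] <- p2$labels
  m <- match_labels(surface_parcellation(unpermuted, 4),
                    surface_parcellation(p1$labels, 4))
  expect_equal(m$accuracy, 1)
})

test_that("noiseless profiles recover the planted cortical networks", {
  sc <- tiny_scene
  run <- tiny_noiseless$runs[[1]]
  nL <- length(sc$cortex_labels_left)
  rois <- sample_rois(nL, nL, n_roi = 300, seed = 44)
  roi_ts <- ts_matrix(run$cortex$values[rois, , drop = FALSE],
                      unit_space = "cortex")
  prof <- compute_profiles(run$cortex, roi_ts)
  # noiseless limit: keep within one network's ROI block (see vignette)
  pl <- binarize_top_fraction(conn_profiles(prof$matrix[1:nL, ]), 0.03)
  est <- cluster_profiles(pl, K = sc$n_networks, restarts = 20, seed = 9,
                          hemisphere = "left")
  m <- match_labels(est, surface_parcellation(sc$cortex_labels_left,
                                              sc$n_networks))
  expect_gte(m$accuracy, 0.99)
})

test_that("gradient maps peak at planted profile boundaries", {
  # path mesh with two homogeneous blocks: only the two boundary
  # vertices see a dissimilar neighbour
  x <- rbind(matrix(rep(c(1, 0), 5), 5, 2, byrow = TRUE),
             matrix(rep(c(0, 1), 4), 4, 2, byrow = TRUE))
  mesh <- cerebparc:::path_mesh(9)
  g <- gradient_map(conn_profiles(x, binarized = TRUE), mesh)
  expect_true(all(g$values[c(5, 6)] > 0))
  expect_equal(g$values[-c(5, 6)], rep(0, 7))
  expect_equal(which(g$values == max(g$values)), c(5L, 6L))
  # identical rows give zero everywhere; an isolated vertex gives zero
  same <- conn_profiles(matrix(1, 4, 3), binarized = TRUE)
  expect_equal(gradient_map(same, cerebparc:::path_mesh(4))$values,
               rep(0, 4))
  lone <- mesh_topology(1, matrix(integer(0), 0, 2))
  expect_equal(gradient_map(conn_profiles(matrix(1, 1, 3),
                                          binarized = TRUE), lone)$values,
               0)
  expect_error(mesh_topology(3, rbind(c(1, 1))), "self-loops")
  expect_error(gradient_map(same, cerebparc:::path_mesh(9)), "match")
})
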