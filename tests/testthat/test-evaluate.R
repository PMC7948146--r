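test_that("overlap percent counts jointly labelled units only", {
  expect_equal(overlap_percent(c(1, 1, 2, 2), c(1, 2, 2, 2))$percent_same_label,
               75)
  r <- overlap_percent(c(1, 1, 2, 0), c(1, 0, 2, 2))
  expect_equal(r$percent_same_label, 100)  # only units 1 and 3 compared
  expect_equal(r$n_compared, 2)
  # symmetry, and 100 iff full agreement on the compared set
  a <- c(1, 2, 3, 1, 2)
  b <- c(1, 3, 3, 1, 1)
  expect_equal(overlap_percent(a, b)$percent_same_label,
               overlap_percent(b, a)$percent_same_label)
  expect_lt(overlap_percent(a, b)$percent_same_label, 100)
  expect_error(overlap_percent(c(0, 0), c(1, 2)), "jointly")
})

test_that("label matching inverts a permutation and is chance-level on noise", {
  set.seed(3)
  ref <- sample.int(6, 500, replace = TRUE)
  perm <- sample(6)
  est <- perm[ref]
  m <- match_labels(est, ref)
  expect_equal(m$accuracy, 1)
  expect_equal(m$labels, ref)
  expect_equal(match_labels(ref, ref)$mapping, 1:6)
  # random labels, K = 2: post-match accuracy about 1/2
  est2 <- sample.int(2, 10000, replace = TRUE)
  ref2 <- sample.int(2, 10000, replace = TRUE)
  expect_equal(match_labels(est2, ref2)$accuracy, 0.5, tolerance = 0.02)
})

test_that("odd sessions go to discovery, even to replication, runs follow sessions", {
  sc <- build_scene(vertices_per_hemisphere = 50,
                    grid_dim = c(8L, 8L, 5L), seed = 2)
  plan31 <- acquisition_plan(n_sessions = 31, runs_per_session = 1,
                             frames_per_run = 4, snr = 0)
  halves <- split_half_protocol(simulate_session_set(sc, plan31, seed = 1))
  sess <- function(h) unique(vapply(h$runs, `[[`, integer(1), "session_id"))
  expect_length(sess(halves$discovery), 16)
  expect_length(sess(halves$replication), 15)
  expect_true(all(sess(halves$discovery) %% 2 == 1))
  # 2 sessions split 1/1; unequal run counts never split a session
  plan2 <- acquisition_plan(n_sessions = 2, runs_per_session = 3,
                            frames_per_run = 4, snr = 0)
  h2 <- split_half_protocol(simulate_session_set(sc, plan2, seed = 1))
  expect_equal(sess(h2$discovery), 1L)
  expect_equal(sess(h2$replication), 2L)
  expect_length(h2$discovery$runs, 3)
  one <- simulate_session_set(sc, acquisition_plan(n_sessions = 1,
                                                   runs_per_session = 2,
                                                   frames_per_run = 4,
                                                   snr = 0), seed = 1)
  expect_error(split_half_protocol(one), "2 sessions")
})

test_that("network composition uses labelled units and sums to one", {
  comp <- network_composition(c(1, 1, 2), K = 2)
  expect_equal(as.numeric(comp), c(2 / 3, 1 / 3))
  expect_equal(as.numeric(network_composition(c(3, 3, 3), K = 3)),
               c(0, 0, 1))
  expect_equal(network_composition(c(1, 1, 2, 0), K = 2),
               network_composition(c(1, 1, 2), K = 2))
  expect_error(network_composition(c(0, 0)), "labelled")
  expect_equal(sum(network_composition(tiny_truth_cereb, K = 10)), 1)
})

test_that("proportionality reports r and the regression line per side", {
  x <- c(0.6, 0.3, 0.1)
  expect_equal(proportionality(x, x)$both$r, 1)
  anti <- proportionality(x, rev(x))
  expect_equal(anti$both$r, cor(x, rev(x)), tolerance = 1e-12)
  expect_equal(anti$both$slope, lm(rev(x) ~ x)$coefficients[[2]])
  # an affinely anti-matched (equally spaced) vector gives r = -1 exactly
  eq <- c(1 / 2, 1 / 3, 1 / 6)
  expect_equal(proportionality(eq, rev(eq))$both$r, -1)
  full <- proportionality(list(left = eq, right = rev(eq)),
                          list(left = eq, right = rev(eq)))
  expect_equal(full$left$r, -1)   # left cerebellum vs right cortex
  expect_equal(full$right$r, -1)
  const <- proportionality(rep(1 / 3, 3), x)
  expect_true(const$both$degenerate)
  expect_error(proportionality(c(0.5, 0.5), c(0.5, 0.5)), "3 networks")
  expect_error(proportionality(c(0.9, 0.3, 0.1), x), "sum to 1")
})

test_that("cerebellar seeds recapitulate their cortical network when seeded back", {
  sc <- tiny_scene
  truth_vec <- tiny_truth_cereb
  target <- 7L  # default-A-like association network
  vox <- which(truth_vec == target & sc$hemisphere_of_voxel == "left")[1]
  out <- seed_to_cortex_validation(
    seed_region("cerebellum_volume", units = vox),
    tiny_noiseless, target = target, cortex_labels = tiny_truth_cortex,
    target_hemisphere = "right")  # contralateral to the left-sided seed
  expect_equal(out$dice, 1)
  expect_gt(out$specificity, 1)

  # two spatially separated representations of one network give more
  # similar cortical maps than any cross-network pair
  reps <- sc$representation_index
  vox_a <- which(truth_vec == target & reps == 1)[1]
  vox_b <- which(truth_vec == target & reps == 2)[1]
  vox_c <- which(truth_vec == 3L & reps == 1)[1]
  zmap <- function(v) seed_to_cortex_validation(
    seed_region("cerebellum_volume", units = v), tiny_noiseless,
    target = target, cortex_labels = tiny_truth_cortex)$z_map$values
  same_net <- cor(zmap(vox_a), zmap(vox_b))
  cross_net <- cor(zmap(vox_a), zmap(vox_c))
  expect_gt(same_net, cross_net)
})

test_that("a pure-noise seed has near-zero specificity", {
  sc <- tiny_scene
  plan <- acquisition_plan(n_sessions = 2, runs_per_session = 1,
                           frames_per_run = 300, snr = 0)
  ss <- simulate_session_set(sc, plan, seed = 61)
  out <- seed_to_cortex_validation(
    seed_region("cerebellum_volume", units = 5L), ss, target = 2L,
    cortex_labels = tiny_truth_cortex)
  # Monte-Carlo error scale: z values are ~N(0, 1/sqrt(T * runs))
  expect_lt(abs(out$specificity), 3 / sqrt(300 * 2))
  expect_lt(out$dice, 0.3)
})
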