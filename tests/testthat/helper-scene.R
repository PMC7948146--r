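# Shared small fixtures, built once per test run.

# Small default-layout subject: 400 vertices/hemisphere, 1080 voxels.
tiny_scene <- build_scene(vertices_per_hemisphere = 400, seed = 101)

# One noiseless run of that subject (series exactly equal the latents).
tiny_noiseless <- simulate_session_set(
  tiny_scene,
  acquisition_plan(n_sessions = 2, runs_per_session = 1,
                   frames_per_run = 200, snr = Inf),
  seed = 102, keep_latents = TRUE)

tiny_truth_cortex <- surface_parcellation(
  c(tiny_scene$cortex_labels_left, tiny_scene$cortex_labels_right),
  tiny_scene$n_networks)

tiny_truth_cereb <- tiny_scene$cerebellum_labels[tiny_scene$cerebellum_mask]

# Brute-force winner-take-all oracle: full sort, explicit vote count,
# explicit tie handling. Kept deliberately naive and separate from the
# implementation.
wta_oracle <- function(z, labels, k) {
  K <- max(labels)
  lab_idx <- which(labels > 0)
  # full stable sort by decreasing z then increasing index
  ord <- lab_idx[order(-z[lab_idx], lab_idx)]
  top <- ord[1:k]
  counts <- sapply(1:K, function(l) sum(labels[top] == l))
  winners <- which(counts == max(counts))
  if (length(winners) > 1) {
    sums <- sapply(winners, function(l) sum(z[top][labels[top] == l]))
    winners <- winners[sums == max(sums)]
  }
  list(label = min(winners), confidence = max(counts) / k)
}

# A ts_matrix from a plain matrix with defaults, for unit tests.
mk_ts <- function(m, tr = 1, space = "cortex") {
  ts_matrix(as.matrix(m), tr_seconds = tr, unit_space = space)
}
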