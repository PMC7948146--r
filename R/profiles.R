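#' Connectivity profiles container
#'
#' A vertices x ROI matrix of correlations (or, after binarization, of
#' 0/1 memberships in the top fraction of each row).
#'
#' @param matrix Numeric vertices x n_roi matrix.
#' @param binarized Logical flag.
#' @param keep_fraction Fraction kept if binarized.
#' @param flagged Optional logical vector marking vertices whose profile
#'   involved degenerate (zero-variance) series.
#' @return An object of class \code{conn_profiles}.
#' @export
conn_profiles <- function(matrix, binarized = FALSE, keep_fraction = NA,
                          flagged = NULL) {
  matrix <- as.matrix(matrix)
  if (!binarized && any(abs(matrix) > 1 + 1e-9)) {
    stop("raw profiles must be correlations in [-1, 1]")
  }
  structure(list(matrix = matrix, n_roi = ncol(matrix),
                 binarized = binarized, keep_fraction = keep_fraction,
                 flagged = flagged %||% rep(FALSE, nrow(matrix))),
            class = "conn_profiles")
}

#' @export
print.conn_profiles <- function(x, ...) {
  cat(sprintf("conn_profiles: %d vertices x %d ROIs (%s)\n",
              nrow(x$matrix), x$n_roi,
              if (x$binarized)
                sprintf("binary, top %.0f%%", 100 * x$keep_fraction)
              else "raw correlations"))
  invisible(x)
}

#' Compute vertex-to-ROI connectivity profiles
#'
#' Pearson correlation between every vertex time course and every ROI
#' time course; the profile of a vertex is its row of correlations to the
#' ROI set. Zero-variance series yield r = 0 and are flagged.
#'
#' @param vertex_ts \code{ts_matrix} of vertex series.
#' @param roi_ts \code{ts_matrix} of ROI series (same timepoints).
#' @return A raw \code{conn_profiles}.
#' @export
compute_profiles <- function(vertex_ts, roi_ts) {
  stopifnot(inherits(vertex_ts, "ts_matrix"), inherits(roi_ts, "ts_matrix"))
  if (n_timepoints(vertex_ts) != n_timepoints(roi_ts)) {
    stop("vertex and ROI series have different numbers of timepoints")
  }
  r <- row_cor(vertex_ts$values, roi_ts$values)
  conn_profiles(unclass(r), binarized = FALSE,
                flagged = attr(r, "degenerate_rows"))
}

#' Sample single-vertex ROIs uniformly across both hemispheres
#'
#' @param n_left,n_right Vertex counts per hemisphere.
#' @param n_roi Number of ROIs (default 1175).
#' @param seed Integer seed.
#' @return Sorted integer indices into the stacked (left then right)
#'   vertex space.
#' @export
sample_rois <- function(n_left, n_right, n_roi = 1175, seed = 1L) {
  total <- n_left + n_right
  if (n_roi > total) stop("more ROIs than vertices")
  with_seed(seed, sort(sample.int(total, n_roi)))
}

#' Binarize profiles by keeping the top fraction per row
#'
#' Each row keeps exactly \code{ceiling(keep_fraction * n_roi)} entries
#' (its largest correlations) as 1 and zeroes the rest. Ties at the
#' cutoff are broken toward the lower ROI index, so binarization is
#' deterministic.
#'
#' @param profiles A raw \code{conn_profiles}.
#' @param keep_fraction Fraction in (0, 1); default 0.10.
#' @return A binary \code{conn_profiles}.
#' @export
binarize_top_fraction <- function(profiles, keep_fraction = 0.10) {
  stopifnot(inherits(profiles, "conn_profiles"))
  if (profiles$binarized) stop("profiles are already binarized")
  if (!(keep_fraction > 0 && keep_fraction < 1)) {
    stop("keep_fraction must be in (0, 1)")
  }
  m <- as.integer(ceiling(keep_fraction * profiles$n_roi))
  if (m == 0L) stop("keep_fraction keeps zero ROIs")
  x <- profiles$matrix
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    out[i, top_k_indices(x[i, ], m)] <- 1
  }
  conn_profiles(out, binarized = TRUE, keep_fraction = keep_fraction,
                flagged = profiles$flagged)
}

#' Surface parcellation container
#'
#' @param labels Integer label per vertex, 1..K with 0 = unassigned.
#' @param K Number of networks.
#' @param hemisphere "left", "right" or "both".
#' @return An object of class \code{surface_parcellation}.
#' @export
surface_parcellation <- function(labels, K, hemisphere = "both") {
  labels <- as.integer(labels)
  if (any(labels < 0L | labels > K)) stop("labels outside 0..K")
  structure(list(labels = labels, K = as.integer(K),
                 hemisphere = hemisphere),
            class = "surface_parcellation")
}

# One spherical k-means pass from given initial centroids.
skmeans_once <- function(x, centers, max_iter = 300, tol = 1e-8) {
  k <- nrow(centers)
  obj_prev <- -Inf
  assign <- rep(1L, nrow(x))
  for (iter in seq_len(max_iter)) {
    sims <- tcrossprod(x, centers)
    assign <- max.col(sims, ties.method = "first")
    best <- sims[cbind(seq_len(nrow(x)), assign)]
    # re-seed empty clusters from the points farthest from their centroid
    empty <- setdiff(seq_len(k), unique(assign))
    if (length(empty) > 0L) {
      far <- order(best)[seq_along(empty)]
      assign[far] <- empty
      best[far] <- 1
    }
    obj <- sum(best)
    for (j in seq_len(k)) {
      v <- colSums(x[assign == j, , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv > 0) centers[j, ] <- v / nv
    }
    if (abs(obj - obj_prev) < tol) break
    obj_prev <- obj
  }
  sims <- tcrossprod(x, centers)
  assign <- max.col(sims, ties.method = "first")
  list(assign = assign, centers = centers,
       objective = sum(sims[cbind(seq_len(nrow(x)), assign)]))
}

# k-means++-style initialization on cosine distance.
skmeans_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) {
    best <- as.numeric(tcrossprod(x, centers[1, , drop = FALSE]))
    for (j in 2L:k) {
      d <- pmax(1 - best, 0)
      p <- d^2
      if (sum(p) <= 0) p <- rep(1, n)
      pick <- sample.int(n, 1L, prob = p)
      centers[j, ] <- x[pick, ]
      best <- pmax(best, as.numeric(tcrossprod(x, centers[j, , drop = FALSE])))
    }
  }
  centers
}

#' Cluster connectivity profiles into K networks
#'
#' Spherical k-means on L2-normalized profile rows: vertices are
#' partitioned to maximize within-cluster cosine similarity to the
#' cluster centroid. This is the group-clustering style of network
#' estimation from binarized connectivity profiles; the best of
#' \code{restarts} k-means++-seeded initializations (by the cosine
#' objective) is returned. Empty clusters are re-seeded from the points
#' least similar to their centroid. Cluster identities are arbitrary;
#' match them to a reference with \code{\link{match_labels}}.
#'
#' @param profiles A \code{conn_profiles} (typically binarized).
#' @param K Number of networks (default 10).
#' @param restarts Number of random restarts (default 20).
#' @param seed Integer seed; deterministic given it.
#' @param hemisphere Stored in the output parcellation.
#' @return A \code{surface_parcellation}; the winning objective is
#'   attached as attribute \code{"objective"}.
#' @export
cluster_profiles <- function(profiles, K = 10, restarts = 20, seed = 1L,
                             hemisphere = "both") {
  stopifnot(inherits(profiles, "conn_profiles"))
  x <- profiles$matrix
  if (nrow(x) < K) stop("fewer vertices than clusters")
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) stop("profiles contain all-zero rows")
  x <- x / norms
  if (K > nrow(unique(x))) stop("K exceeds the number of distinct profiles")
  if (K == 1L) {
    out <- surface_parcellation(rep(1L, nrow(x)), 1L, hemisphere)
    attr(out, "objective") <- nrow(x)
    return(out)
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- skmeans_once(x, skmeans_init(x, K))
      if (is.null(best) || fit$objective > best$objective) best <- fit
    }
  })
  out <- surface_parcellation(best$assign, K, hemisphere)
  attr(out, "objective") <- best$objective
  out
}

#' Mesh topology for gradient computation
#'
#' @param n_vertices Vertex count.
#' @param edges Integer 2-column matrix of undirected edges.
#' @return An object of class \code{mesh_topology}.
#' @export
mesh_topology <- function(n_vertices, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > n_vertices)) {
      stop("edges reference invalid vertices")
    }
    if (any(edges[, 1] == edges[, 2])) stop("self-loops not allowed")
  }
  structure(list(n_vertices = as.integer(n_vertices), edges = edges),
            class = "mesh_topology")
}

# Chain mesh over n vertices (useful default and test geometry).
path_mesh <- function(n) {
  mesh_topology(n, cbind(seq_len(n - 1), 2:n))
}

#' Connectivity-gradient map over a mesh
#'
#' For each vertex, the mean cosine dissimilarity (1 - cosine
#' similarity) between its connectivity profile and those of its mesh
#' neighbours. Sharp network boundaries appear as ridges of high
#' gradient; isolated vertices get 0.
#'
#' @param profiles A \code{conn_profiles} with one row per mesh vertex.
#' @param mesh A \code{mesh_topology}.
#' @return A \code{scalar_map} with statistic "gradient".
#' @export
gradient_map <- function(profiles, mesh) {
  stopifnot(inherits(profiles, "conn_profiles"),
            inherits(mesh, "mesh_topology"))
  x <- profiles$matrix
  if (nrow(x) != mesh$n_vertices) {
    stop("profile rows do not match mesh vertices")
  }
  norms <- sqrt(rowSums(x^2))
  safe <- ifelse(norms == 0, 1, norms)
  xn <- x / safe
  grad <- numeric(nrow(x))
  count <- numeric(nrow(x))
  if (nrow(mesh$edges) > 0) {
    a <- mesh$edges[, 1]; b <- mesh$edges[, 2]
    d <- 1 - rowSums(xn[a, , drop = FALSE] * xn[b, , drop = FALSE])
    for (e in seq_along(d)) {
      grad[a[e]] <- grad[a[e]] + d[e]; count[a[e]] <- count[a[e]] + 1
      grad[b[e]] <- grad[b[e]] + d[e]; count[b[e]] <- count[b[e]] + 1
    }
  }
  grad <- ifelse(count > 0, grad / pmax(count, 1), 0)
  scalar_map(grad, "gradient", unit_space = "cortex")
}
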