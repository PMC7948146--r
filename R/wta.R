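#' Volume parcellation container
#'
#' @param labels Integer 3-D array of network labels (0 outside the mask
#'   or unassigned).
#' @param K Number of networks.
#' @param mask Logical 3-D array marking in-mask voxels.
#' @param spacing_mm Isotropic voxel size.
#' @param origin_mm mm-coordinate of the first voxel centre.
#' @param confidence Optional numeric array of winner vote fractions.
#' @return An object of class \code{volume_parcellation}.
#' @export
volume_parcellation <- function(labels, K, mask = NULL, spacing_mm = 2,
                                origin_mm = c(0, 0, 0),
                                confidence = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(labels))
  stopifnot(identical(dim(labels), dim(mask)))
  if (any(labels[mask] < 0L | labels[mask] > K)) {
    stop("in-mask labels outside 0..K")
  }
  if (any(labels[!mask] != 0L)) stop("nonzero labels outside the mask")
  structure(list(labels = labels, K = as.integer(K), mask = mask,
                 spacing_mm = spacing_mm, origin_mm = origin_mm,
                 confidence = confidence),
            class = "volume_parcellation")
}

#' @export
print.volume_parcellation <- function(x, ...) {
  lab <- x$labels[x$mask]
  cat(sprintf("volume_parcellation: %s grid, %d in-mask voxels, %d/%d networks used\n",
              paste(dim(x$labels), collapse = "x"), sum(x$mask),
              length(unique(lab[lab > 0])), x$K))
  invisible(x)
}

#' Run-averaged voxel-to-vertex connectivity
#'
#' For each run, Pearson correlation between every cerebellar voxel and
#' every cortical vertex, Fisher r-to-z transformed; the z values are
#' then averaged elementwise across runs. Optionally computed in voxel
#' blocks to bound memory; blocked and monolithic computation give
#' identical results.
#'
#' @param runs A \code{session_set}, or a list of runs each carrying
#'   \code{cortex} and \code{cerebellum} \code{ts_matrix} elements.
#' @param block_size Number of voxel rows per block (default all).
#' @return An object of class \code{voxel_vertex_conn} with elements
#'   \code{z} (voxels x vertices), \code{hemisphere} (per vertex) and
#'   \code{n_runs}.
#' @export
voxel_vertex_connectivity <- function(runs, block_size = Inf) {
  if (inherits(runs, "session_set")) runs <- runs$runs
  stopifnot(length(runs) >= 1L)
  nv <- n_units(runs[[1]]$cerebellum)
  nc <- n_units(runs[[1]]$cortex)
  for (r in runs) {
    if (n_units(r$cerebellum) != nv || n_units(r$cortex) != nc ||
        r$cortex$unit_space != runs[[1]]$cortex$unit_space) {
      stop("runs have inconsistent unit spaces")
    }
  }
  acc <- matrix(0, nv, nc)
  for (r in runs) {
    starts <- seq(1L, nv, by = min(block_size, nv))
    for (s in starts) {
      rows <- s:min(s + block_size - 1, nv)
      rr <- row_cor(r$cerebellum$values[rows, , drop = FALSE],
                    r$cortex$values)
      acc[rows, ] <- acc[rows, ] + fisher_z(unclass(rr))
    }
  }
  structure(list(z = acc / length(runs),
                 hemisphere = runs[[1]]$cortex$hemisphere,
                 n_runs = length(runs)),
            class = "voxel_vertex_conn")
}

#' Winner-take-all assignment of one voxel
#'
#' Selects the k cortical vertices with the largest connectivity to the
#' voxel (ties at the cutoff broken toward the lower vertex index) among
#' labelled vertices, and assigns the voxel the most frequent network
#' among them. Vote ties are broken first toward the network with the
#' larger summed z among its voting vertices, then toward the smaller
#' network index. Confidence is the winning vote count divided by k.
#'
#' @param z Numeric vector of connectivity values, one per vertex.
#' @param labels A \code{surface_parcellation} or integer label vector
#'   (0 = unlabelled, excluded from voting).
#' @param k Number of voting vertices (default 400).
#' @return List with \code{label} and \code{confidence}.
#' @export
wta_assign_voxel <- function(z, labels, k = 400) {
  if (inherits(labels, "surface_parcellation")) {
    K <- labels$K
    labels <- labels$labels
  } else {
    labels <- as.integer(labels)
    K <- max(labels)
  }
  stopifnot(length(z) == length(labels))
  labelled <- which(labels > 0L)
  if (k < 1L || k > length(labelled)) {
    stop(sprintf("k = %d outside 1..%d labelled vertices", k,
                 length(labelled)))
  }
  ord <- labelled[order(-z[labelled], labelled)]
  top <- ord[seq_len(k)]
  mode <- label_mode(labels[top], z[top], K)
  list(label = mode[1L], confidence = mode[2L] / k)
}

#' Parcellate the cerebellum by top-k winner-take-all
#'
#' Applies \code{\link{wta_assign_voxel}} independently to every in-mask
#' voxel of a run-averaged voxel-to-vertex connectivity matrix. By
#' default all labelled vertices from both hemispheres vote; with
#' \code{contralateral_only} each voxel's vote is restricted to the
#' cortical hemisphere opposite its own.
#'
#' @param conn A \code{voxel_vertex_conn}.
#' @param labels A \code{surface_parcellation} over the same vertices.
#' @param k Number of voting vertices (default 400).
#' @param scene Optional \code{gt_scene} supplying grid geometry and
#'   voxel hemispheres; without it the output grid is a 1-D stack of the
#'   connectivity rows.
#' @param contralateral_only Restrict voting to the contralateral
#'   cortical hemisphere (requires hemisphere tables).
#' @return A \code{volume_parcellation} with a confidence map.
#' @export
parcellate_cerebellum <- function(conn, labels, k = 400, scene = NULL,
                                  contralateral_only = FALSE) {
  stopifnot(inherits(conn, "voxel_vertex_conn"),
            inherits(labels, "surface_parcellation"))
  nvox <- nrow(conn$z)
  lab_vec <- labels$labels
  if (length(lab_vec) != ncol(conn$z)) {
    stop("cortical labels do not match connectivity columns")
  }
  voxel_hemi <- NULL
  if (contralateral_only) {
    if (is.null(conn$hemisphere) || is.null(scene)) {
      stop("contralateral-only voting needs vertex and voxel hemispheres")
    }
    voxel_hemi <- scene$hemisphere_of_voxel
  }
  out_lab <- integer(nvox)
  out_conf <- numeric(nvox)
  for (v in seq_len(nvox)) {
    lv <- lab_vec
    if (contralateral_only) {
      contra <- if (voxel_hemi[v] == "left") "right" else "left"
      lv[conn$hemisphere != contra] <- 0L
    }
    a <- wta_assign_voxel(conn$z[v, ], surface_parcellation(lv, labels$K),
                          k = min(k, sum(lv > 0L)))
    out_lab[v] <- a$label
    out_conf[v] <- a$confidence
  }
  if (is.null(scene)) {
    arr <- array(out_lab, dim = c(nvox, 1L, 1L))
    conf <- array(out_conf, dim = c(nvox, 1L, 1L))
    return(volume_parcellation(arr, labels$K, confidence = conf))
  }
  arr <- array(0L, scene$grid_dim)
  arr[scene$cerebellum_mask] <- out_lab
  conf <- array(0, scene$grid_dim)
  conf[scene$cerebellum_mask] <- out_conf
  volume_parcellation(arr, labels$K, mask = scene$cerebellum_mask,
                      spacing_mm = scene$spacing_mm,
                      origin_mm = scene$origin_mm, confidence = conf)
}
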