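#' Outer/inner surface correspondence for flatmap projection
#'
#' Each flatmap vertex has a corresponding point on the outer
#' (gray-matter) and inner (white-matter) cerebellar surfaces; labels are
#' projected by sampling the segment joining the two.
#'
#' @param outer,inner Numeric n x 3 matrices of mm coordinates.
#' @return An object of class \code{surface_correspondence}.
#' @export
surface_correspondence <- function(outer, inner) {
  outer <- as.matrix(outer); inner <- as.matrix(inner)
  stopifnot(ncol(outer) == 3L, ncol(inner) == 3L,
            nrow(outer) == nrow(inner))
  if (anyNA(outer) || anyNA(inner) ||
      any(!is.finite(outer)) || any(!is.finite(inner))) {
    stop("correspondence coordinates must be finite")
  }
  structure(list(outer = outer, inner = inner, n = nrow(outer)),
            class = "surface_correspondence")
}

#' Project volumetric labels onto a surface by segment majority vote
#'
#' For each flatmap vertex, \code{n_samples} points are placed evenly on
#' the closed segment from its outer-surface to its inner-surface
#' coordinate (endpoints included; a degenerate segment samples a single
#' point). Each sample is mapped to the nearest voxel centre; the vertex
#' receives the most frequent nonzero in-mask label among the samples,
#' ties broken toward the smaller network index. If no sample hits a
#' labelled in-mask voxel the vertex is left unassigned (0).
#'
#' @param volume A \code{volume_parcellation}.
#' @param corr A \code{surface_correspondence}.
#' @param n_samples Samples per segment (default 21, >= 2).
#' @return Integer label vector, one per flatmap vertex.
#' @export
project_volume_labels <- function(volume, corr, n_samples = 21) {
  stopifnot(inherits(volume, "volume_parcellation"),
            inherits(corr, "surface_correspondence"))
  if (n_samples < 2L) stop("n_samples must be >= 2")
  dims <- dim(volume$labels)
  tvals <- seq(0, 1, length.out = n_samples)
  out <- integer(corr$n)
  for (v in seq_len(corr$n)) {
    seg <- outer(1 - tvals, corr$outer[v, ]) + outer(tvals, corr$inner[v, ])
    # nearest voxel centre (centres at origin + spacing * (index - 1));
    # a sample exactly midway between two centres maps to the higher index
    ijk <- floor(sweep(seg, 2, volume$origin_mm) / volume$spacing_mm + 0.5) + 1
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
      ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- ijk[ok, 1] + dims[1] * (ijk[ok, 2] - 1) +
      dims[1] * dims[2] * (ijk[ok, 3] - 1)
    labs <- volume$labels[lin][volume$mask[lin]]
    labs <- labs[labs > 0L]
    if (length(labs) == 0L) next
    votes <- tabulate(labs, nbins = volume$K)
    out[v] <- which.max(votes)  # which.max takes the smallest index on ties
  }
  out
}
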