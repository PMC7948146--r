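#' Per-unit scalar map
#'
#' Holds one scalar per unit (correlation, Fisher z, gradient, or
#' confidence) together with a validity mask: units whose statistic is
#' undefined (for example zero-variance series) carry value 0 and
#' \code{mask = FALSE}.
#'
#' @param values Numeric vector, one value per unit.
#' @param statistic One of "r", "z", "z_diff", "gradient", "confidence".
#' @param mask Logical validity vector (default all TRUE).
#' @param unit_space Unit space the map lives in.
#' @return An object of class \code{scalar_map}.
#' @export
scalar_map <- function(values, statistic = c("r", "z", "z_diff",
                                             "gradient", "confidence"),
                       mask = NULL, unit_space = "cortex") {
  statistic <- match.arg(statistic)
  values <- as.numeric(values)
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  stopifnot(length(mask) == length(values))
  if (statistic == "r" && any(abs(values[mask]) > 1 + 1e-9)) {
    stop("correlation values outside [-1, 1]")
  }
  structure(list(values = values, statistic = statistic, mask = mask,
                 unit_space = unit_space), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("scalar_map(%s): %d units (%d valid), range [%.4g, %.4g]\n",
              x$statistic, length(x$values), sum(x$mask),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Define a seed region
#'
#' A seed is either an explicit set of unit indices (e.g. single vertices
#' on a surface) or a sphere of given centre and radius in mm on the
#' volume grid. Sphere membership includes voxels whose centre lies at
#' distance exactly equal to the radius.
#'
#' @param space Unit space the seed lives in.
#' @param units Integer unit indices (within the hemisphere for
#'   \code{cortex_left}/\code{cortex_right}).
#' @param center_mm,radius_mm Sphere definition for volume seeds.
#' @return An object of class \code{seed_region}.
#' @export
seed_region <- function(space = c("cortex_left", "cortex_right",
                                  "cortex", "cerebellum_volume"),
                        units = NULL, center_mm = NULL, radius_mm = NULL) {
  space <- match.arg(space)
  if (is.null(units) && (is.null(center_mm) || is.null(radius_mm))) {
    stop("give either explicit units or a (center_mm, radius_mm) sphere")
  }
  if (!is.null(center_mm)) stopifnot(length(center_mm) == 3, radius_mm > 0)
  structure(list(space = space, units = units, center_mm = center_mm,
                 radius_mm = radius_mm), class = "seed_region")
}

# Resolve a seed to row indices of a ts_matrix. `coords` (units x 3, mm)
# is required for sphere seeds.
resolve_seed <- function(seed, ts, coords = NULL) {
  stopifnot(inherits(seed, "seed_region"), inherits(ts, "ts_matrix"))
  if (!is.null(seed$units)) {
    if (seed$space %in% c("cortex_left", "cortex_right") &&
        ts$unit_space == "cortex") {
      if (is.null(ts$hemisphere)) {
        stop("ts has no hemisphere table; cannot resolve hemispheric seed")
      }
      hemi <- sub("cortex_", "", seed$space)
      rows <- which(ts$hemisphere == hemi)[seed$units]
    } else if (seed$space == ts$unit_space ||
               (seed$space == "cortex" &&
                ts$unit_space %in% c("cortex_left", "cortex_right"))) {
      rows <- seed$units
    } else {
      stop(sprintf("seed space '%s' does not resolve in ts space '%s'",
                   seed$space, ts$unit_space))
    }
  } else {
    if (is.null(coords)) stop("sphere seeds need unit coordinates")
    stopifnot(nrow(coords) == n_units(ts))
    d2 <- colSums((t(coords) - seed$center_mm)^2)
    rows <- which(d2 <= seed$radius_mm^2 + 1e-9)
  }
  if (length(rows) == 0L || anyNA(rows)) stop("seed resolves to no units")
  if (any(rows < 1L | rows > n_units(ts))) stop("seed units out of bounds")
  rows
}

#' Mean time course over a seed region
#'
#' @param ts A \code{ts_matrix}.
#' @param seed A \code{seed_region}.
#' @param coords Optional units x 3 mm-coordinate matrix (needed for
#'   sphere seeds).
#' @return Numeric vector of length timepoints: the unweighted mean
#'   across seed units.
#' @export
seed_timecourse <- function(ts, seed, coords = NULL) {
  rows <- resolve_seed(seed, ts, coords)
  colMeans(ts$values[rows, , drop = FALSE])
}

#' Seed-based correlation map
#'
#' Pearson correlation between a seed time course and every unit of a
#' target time-series matrix. Units with zero variance get r = 0 and are
#' flagged invalid in the map's mask, so downstream voting stays total.
#'
#' @param target A \code{ts_matrix}.
#' @param seed_series Numeric vector, one value per timepoint.
#' @return A \code{scalar_map} with statistic "r".
#' @export
correlation_map <- function(target, seed_series) {
  stopifnot(inherits(target, "ts_matrix"))
  if (length(seed_series) != n_timepoints(target)) {
    stop(sprintf("seed series has %d timepoints, target has %d",
                 length(seed_series), n_timepoints(target)))
  }
  if (stats::sd(seed_series) == 0) stop("seed series has zero variance")
  r <- row_cor(target$values, matrix(seed_series, nrow = 1))
  scalar_map(as.numeric(r), "r",
             mask = !attr(r, "degenerate_rows"),
             unit_space = target$unit_space)
}

#' Fisher r-to-z transform
#'
#' \code{z = atanh(r)}, after clamping |r| to \code{1 - 1e-7} so that
#' perfect correlations map to a large finite value rather than Inf.
#' Values with |r| beyond 1 (allowing 1e-9 numerical slack) are an error.
#'
#' @param x A \code{scalar_map} with statistic "r", or a numeric vector.
#' @return Same shape as the input, transformed; maps get statistic "z".
#' @export
fisher_z <- function(x) {
  tf <- function(r) {
    if (any(abs(r) > 1 + 1e-9)) stop("|r| > 1 in fisher_z input")
    atanh(pmax(pmin(r, 1 - 1e-7), -1 + 1e-7))
  }
  if (inherits(x, "scalar_map")) {
    stopifnot(x$statistic == "r")
    out <- x
    out$values <- tf(x$values)
    out$statistic <- "z"
    out
  } else {
    tf(x)
  }
}

#' Average scalar maps across runs
#'
#' Elementwise arithmetic mean; typically applied to Fisher-z maps, one
#' per run. The output mask is the intersection of the input masks.
#'
#' @param maps List of \code{scalar_map}s over the same unit space.
#' @return A \code{scalar_map}.
#' @export
average_maps <- function(maps) {
  if (inherits(maps, "scalar_map")) maps <- list(maps)
  stopifnot(length(maps) >= 1L)
  space <- maps[[1]]$unit_space
  stat <- maps[[1]]$statistic
  n <- length(maps[[1]]$values)
  for (m in maps) {
    if (m$unit_space != space) stop("maps live in different unit spaces")
    if (length(m$values) != n) stop("maps have different lengths")
  }
  vals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  mask <- Reduce(`&`, lapply(maps, `[[`, "mask"))
  scalar_map(vals, stat, mask = mask, unit_space = space)
}

#' Difference between two scalar maps
#'
#' Elementwise \code{a - b}; used e.g. for the left-hand minus right-hand
#' seed contrast revealing contralateral cerebellar somatomotor zones.
#'
#' @param a,b \code{scalar_map}s over the same unit space.
#' @return A \code{scalar_map} with statistic "z_diff".
#' @export
contrast_maps <- function(a, b) {
  stopifnot(inherits(a, "scalar_map"), inherits(b, "scalar_map"))
  if (a$unit_space != b$unit_space || length(a$values) != length(b$values)) {
    stop("maps live in different unit spaces")
  }
  scalar_map(a$values - b$values, "z_diff", mask = a$mask & b$mask,
             unit_space = a$unit_space)
}

#' Threshold several z maps into a multi-label overlay
#'
#' For each named map, units with \code{z >= threshold[name]} get that
#' map's bit set; bits are independent, so a unit can belong to several
#' overlays (e.g. foot, hand and tongue somatomotor maps at thresholds
#' 0.1, 0.2 and 0.1).
#'
#' @param maps Named list of \code{scalar_map}s.
#' @param thresholds Named numeric vector with one entry per map name.
#' @return List with \code{bits} (integer bitmask per unit, bit i for the
#'   i-th map), \code{members} (named list of logical vectors), and
#'   \code{names}.
#' @export
threshold_overlay <- function(maps, thresholds) {
  stopifnot(length(maps) >= 1L, !is.null(names(maps)))
  missing <- setdiff(names(maps), names(thresholds))
  if (length(missing) > 0L) {
    stop("no threshold for map(s): ", paste(missing, collapse = ", "))
  }
  n <- length(maps[[1]]$values)
  bits <- integer(n)
  members <- list()
  for (i in seq_along(maps)) {
    nm <- names(maps)[i]
    hit <- maps[[nm]]$values >= thresholds[[nm]]
    members[[nm]] <- hit
    bits <- bits + bitwShiftL(1L, i - 1L) * as.integer(hit)
  }
  list(bits = bits, members = members, names = names(maps))
}
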