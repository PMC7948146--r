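# Readers and writers for the formats the pipeline touches: NIfTI-1
# volumes, plain-text per-vertex label tables, CSV correspondence tables
# and YAML/JSON configuration. Conventions: voxel array indices are
# 1-based in R; mm coordinates are voxel centres at
# origin + spacing * (index - 1).

#' Write a label or scalar volume as NIfTI-1
#'
#' Integer label volumes are stored with an integer datatype, scalar maps
#' as float32. Grid spacing and origin are encoded in the qform/sform.
#'
#' @param data 3-D array, or a \code{volume_parcellation} (its labels are
#'   written and \code{spacing_mm}/\code{origin_mm} are taken from it).
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param spacing_mm,origin_mm Grid geometry for plain arrays.
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, spacing_mm = 2,
                         origin_mm = c(0, 0, 0)) {
  if (inherits(data, "volume_parcellation")) {
    spacing_mm <- data$spacing_mm
    origin_mm <- data$origin_mm
    data <- data$labels
  }
  stopifnot(length(dim(data)) == 3L)
  is_int <- is.integer(data) || all(data == round(data))
  img <- RNifti::asNifti(if (is_int) array(as.integer(data), dim(data))
                         else data)
  RNifti::pixdim(img) <- rep(spacing_mm, 3)
  m <- diag(c(rep(spacing_mm, 3), 1))
  m[1:3, 4] <- origin_mm
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path,
                     datatype = if (is_int) "int32" else "float")
  invisible(path)
}

#' Read a NIfTI-1 volume with its grid geometry
#'
#' @param path Path to a \code{.nii}/\code{.nii.gz} file.
#' @param expect_grid Optional list with \code{dim}, \code{spacing_mm}
#'   and \code{origin_mm}; a mismatch is an error naming both grids.
#' @return List with \code{data} (3-D array), \code{spacing_mm} and
#'   \code{origin_mm}.
#' @export
read_volume <- function(path, expect_grid = NULL) {
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1]
  origin <- as.numeric(x[1:3, 4])
  out <- list(data = as.array(img), spacing_mm = spacing,
              origin_mm = origin)
  if (!is.null(expect_grid)) {
    got <- sprintf("%s @ %g mm, origin (%s)",
                   paste(dim(out$data), collapse = "x"), spacing,
                   paste(signif(origin, 6), collapse = ", "))
    want <- sprintf("%s @ %g mm, origin (%s)",
                    paste(expect_grid$dim, collapse = "x"),
                    expect_grid$spacing_mm,
                    paste(signif(expect_grid$origin_mm, 6), collapse = ", "))
    if (!identical(dim(out$data), as.integer(expect_grid$dim)) ||
        abs(spacing - expect_grid$spacing_mm) > 1e-5 ||
        any(abs(origin - expect_grid$origin_mm) > 1e-4)) {
      stop(sprintf("volume grid mismatch: file has %s, expected %s",
                   got, want))
    }
  }
  out
}

#' Write / read a per-vertex label table
#'
#' Plain text, one integer label per line.
#'
#' @param labels Integer vector or \code{surface_parcellation}.
#' @param path File path.
#' @return \code{write_labels}: the path, invisibly; \code{read_labels}:
#'   an integer vector.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "surface_parcellation")) labels <- labels$labels
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  as.integer(readLines(path))
}

#' Write / read an outer/inner surface correspondence table
#'
#' Six-column CSV: outer x, y, z then inner x, y, z, one flatmap vertex
#' per row.
#'
#' @param corr A \code{surface_correspondence}.
#' @param path File path.
#' @return \code{write_correspondence}: the path, invisibly;
#'   \code{read_correspondence}: a \code{surface_correspondence}.
#' @export
write_correspondence <- function(corr, path) {
  stopifnot(inherits(corr, "surface_correspondence"))
  df <- data.frame(outer_x = corr$outer[, 1], outer_y = corr$outer[, 2],
                   outer_z = corr$outer[, 3], inner_x = corr$inner[, 1],
                   inner_y = corr$inner[, 2], inner_z = corr$inner[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_correspondence
#' @export
read_correspondence <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(ncol(df) >= 6L)
  surface_correspondence(as.matrix(df[, 1:3]), as.matrix(df[, 4:6]))
}

#' Serialize a synthetic scene to disk
#'
#' Writes the cerebellar label volume as NIfTI, per-hemisphere cortical
#' label tables as plain text, and a JSON sidecar holding the generating
#' parameters and seed.
#'
#' @param scene A \code{gt_scene}.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
save_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "gt_scene"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(array(as.integer(scene$cerebellum_labels), scene$grid_dim),
               file.path(dir, "cerebellum_labels.nii.gz"),
               spacing_mm = scene$spacing_mm, origin_mm = scene$origin_mm)
  write_labels(scene$cortex_labels_left,
               file.path(dir, "cortex_labels_left.txt"))
  write_labels(scene$cortex_labels_right,
               file.path(dir, "cortex_labels_right.txt"))
  sidecar <- list(n_networks = scene$n_networks,
                  network_names = scene$network_names,
                  grid_dim = scene$grid_dim,
                  spacing_mm = scene$spacing_mm,
                  origin_mm = scene$origin_mm,
                  network_fractions = as.data.frame(scene$network_fractions),
                  lateralization = scene$lateralization,
                  somatomotor = scene$somatomotor,
                  language = scene$language,
                  body_part_coupling = scene$body_part_coupling,
                  rng_seed = scene$rng_seed)
  jsonlite::write_json(sidecar, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

config_defaults <- function() {
  list(K = 10L, k = 400L, keep_fraction = 0.10, restarts = 20L,
       band_low_hz = 0.01, band_high_hz = 0.1,
       motion_limit_mm = 2, tsnr_floor = 130,
       threshold_foot = 0.1, threshold_hand = 0.2, threshold_tongue = 0.1,
       flatmap_samples = 21L)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration file, fills in defaults for absent
#' keys (k = 400, keep_fraction = 0.10, K = 10, band 0.01-0.1 Hz, overlay
#' thresholds foot/hand/tongue = 0.1/0.2/0.1, motion limit 2 mm, tSNR
#' floor 130), rejects unknown keys, and checks ranges.
#'
#' @param path Optional path; NULL gives the full default set.
#' @return Named list of validated parameters.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(user) > 0) {
      unknown <- setdiff(names(user), names(cfg))
      if (length(unknown) > 0L) {
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
      }
      cfg[names(user)] <- user
    }
  }
  bad <- character(0)
  if (cfg$K < 1) bad <- c(bad, "K")
  if (cfg$k < 1) bad <- c(bad, "k")
  if (!(cfg$keep_fraction > 0 && cfg$keep_fraction < 1)) {
    bad <- c(bad, "keep_fraction")
  }
  if (cfg$restarts < 1) bad <- c(bad, "restarts")
  if (!(cfg$band_low_hz >= 0 && cfg$band_low_hz < cfg$band_high_hz)) {
    bad <- c(bad, "band_low_hz/band_high_hz")
  }
  if (cfg$motion_limit_mm < 0) bad <- c(bad, "motion_limit_mm")
  if (cfg$tsnr_floor < 0) bad <- c(bad, "tsnr_floor")
  if (cfg$flatmap_samples < 2) bad <- c(bad, "flatmap_samples")
  if (length(bad) > 0L) {
    stop("configuration values out of range: ", paste(bad, collapse = ", "))
  }
  cfg
}
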