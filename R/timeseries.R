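#' Construct a units-by-timepoints time-series matrix
#'
#' The basic signal container: one row per unit (cortical vertex or
#' cerebellar voxel), one column per frame.
#'
#' @param values Numeric matrix, units x timepoints; no missing values.
#' @param tr_seconds Repetition time in seconds (> 0).
#' @param unit_space One of \code{"cortex"}, \code{"cortex_left"},
#'   \code{"cortex_right"}, \code{"cerebellum_volume"}.
#' @param run_id,session_id Identifiers carried through the pipeline.
#' @param hemisphere Optional per-unit hemisphere vector ("left"/"right"),
#'   used when \code{unit_space = "cortex"} holds both hemispheres.
#' @return An object of class \code{ts_matrix}.
#' @export
ts_matrix <- function(values, tr_seconds = 1,
                      unit_space = c("cortex", "cortex_left",
                                     "cortex_right", "cerebellum_volume"),
                      run_id = "run1", session_id = 1L,
                      hemisphere = NULL) {
  unit_space <- match.arg(unit_space)
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("time series contain missing or non-finite values")
  }
  if (ncol(values) < 2L) stop("need at least 2 timepoints")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    stop("tr_seconds must be positive")
  }
  if (!is.null(hemisphere)) stopifnot(length(hemisphere) == nrow(values))
  structure(list(values = values, tr_seconds = tr_seconds,
                 unit_space = unit_space, run_id = run_id,
                 session_id = session_id, hemisphere = hemisphere),
            class = "ts_matrix")
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("ts_matrix: %d units x %d timepoints (%s, TR %gs, %s)\n",
              nrow(x$values), ncol(x$values), x$unit_space,
              x$tr_seconds, x$run_id))
  invisible(x)
}

n_timepoints <- function(ts) ncol(ts$values)
n_units <- function(ts) nrow(ts$values)

# Replace values, keeping metadata.
ts_with_values <- function(ts, values) {
  ts$values <- values
  ts
}
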