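#' Run-level quality-control record
#'
#' @param run_id Run identifier.
#' @param max_abs_motion_mm Maximum absolute head motion over the run, mm.
#' @param tsnr Slice-based temporal signal-to-noise ratio of the run.
#' @return An object of class \code{run_qc_record}.
#' @export
run_qc_record <- function(run_id, max_abs_motion_mm, tsnr) {
  if (!is.finite(max_abs_motion_mm) || max_abs_motion_mm < 0) {
    stop("max_abs_motion_mm must be finite and >= 0")
  }
  if (!is.finite(tsnr) || tsnr < 0) stop("tsnr must be finite and >= 0")
  structure(list(run_id = run_id,
                 max_abs_motion_mm = max_abs_motion_mm, tsnr = tsnr),
            class = "run_qc_record")
}

#' Partition runs into kept and excluded by QC rules
#'
#' A run is excluded iff its maximum absolute motion exceeds
#' \code{motion_limit_mm} (strictly more than the limit) OR its temporal
#' SNR is less than or equal to \code{tsnr_floor}. Both comparisons are
#' applied exactly as stated: motion exactly at the limit is kept, tSNR
#' exactly at the floor is excluded.
#'
#' @param records List of \code{run_qc_record}s.
#' @param motion_limit_mm Motion exclusion limit in mm (default 2).
#' @param tsnr_floor tSNR exclusion floor (default 130).
#' @return List with character vectors \code{kept} and \code{excluded}
#'   of run ids, covering all input runs.
#' @export
run_qc <- function(records, motion_limit_mm = 2, tsnr_floor = 130) {
  if (length(records) == 0L) stop("no QC records supplied")
  if (inherits(records, "run_qc_record")) records <- list(records)
  ids <- vapply(records, function(r) as.character(r$run_id), character(1))
  motion <- vapply(records, function(r) r$max_abs_motion_mm, numeric(1))
  tsnr <- vapply(records, function(r) r$tsnr, numeric(1))
  if (any(motion < 0) || any(tsnr < 0)) {
    stop("negative motion or tsnr in QC records")
  }
  excl <- motion > motion_limit_mm | tsnr <= tsnr_floor
  list(kept = ids[!excl], excluded = ids[excl])
}

#' Apply QC to a session set
#'
#' Drops runs failing \code{\link{run_qc}} from a \code{session_set}.
#'
#' @inheritParams run_qc
#' @param sessions A \code{session_set}.
#' @return The session set with excluded runs removed; the QC partition
#'   is attached as attribute \code{"qc"}.
#' @export
apply_qc <- function(sessions, motion_limit_mm = 2, tsnr_floor = 130) {
  stopifnot(inherits(sessions, "session_set"))
  part <- run_qc(lapply(sessions$runs, `[[`, "qc"),
                 motion_limit_mm, tsnr_floor)
  keep <- vapply(sessions$runs, function(r) r$run_id %in% part$kept,
                 logical(1))
  sessions$runs <- sessions$runs[keep]
  attr(sessions, "qc") <- part
  sessions
}

#' Regress nuisance signals out of a time-series matrix
#'
#' Projects each unit's series onto the orthogonal complement of the
#' column space of \code{regressors}. An intercept column is always
#' included, so residuals are demeaned. Rank-deficient designs are
#' handled through the pseudo-inverse with a warning.
#'
#' @param ts A \code{ts_matrix}.
#' @param regressors Numeric timepoints x q matrix of nuisance series
#'   (motion parameters, global/ventricular/white-matter signals, ...).
#' @return The residual \code{ts_matrix}.
#' @export
regress_nuisance <- function(ts, regressors) {
  stopifnot(inherits(ts, "ts_matrix"))
  regressors <- as.matrix(regressors)
  t_n <- n_timepoints(ts)
  if (nrow(regressors) != t_n) {
    stop(sprintf("regressors have %d rows but the series has %d timepoints",
                 nrow(regressors), t_n))
  }
  if (ncol(regressors) >= t_n) stop("more regressors than timepoints")
  x <- cbind(intercept = 1, regressors)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    warning("rank-deficient nuisance design; using pseudo-inverse")
    sv <- svd(x)
    pos <- sv$d > max(dim(x)) * .Machine$double.eps * sv$d[1]
    hat_t <- sv$u[, pos, drop = FALSE] %*% t(sv$u[, pos, drop = FALSE])
    resid <- ts$values - ts$values %*% hat_t
  } else {
    # residuals of Y' ~ X, computed for all units at once
    resid <- t(qr.resid(qx, t(ts$values)))
  }
  ts_with_values(ts, resid)
}

#' Zero-phase band-pass filter
#'
#' Filters each unit's series to the \code{[low_hz, high_hz]} band by
#' frequency-domain masking: Fourier coefficients at frequencies inside
#' the band (inclusive) are kept, all others — including DC — are zeroed.
#' Masking a real spectrum symmetrically applies no phase shift, and the
#' amplitude response is exactly 1 in the pass band and 0 elsewhere at
#' the Fourier frequencies.
#'
#' @param ts A \code{ts_matrix}.
#' @param low_hz,high_hz Band edges in Hz; defaults 0.01 and 0.1, the
#'   conventional resting-state band.
#' @return The filtered \code{ts_matrix}.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(ts, "ts_matrix"))
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(sprintf("band [%g, %g] Hz invalid for Nyquist %g Hz",
                 low_hz, high_hz, nyquist))
  }
  t_n <- n_timepoints(ts)
  freqs <- (seq_len(t_n) - 1) / (t_n * ts$tr_seconds)
  freqs <- pmin(freqs, 1 / ts$tr_seconds - freqs)
  keep <- freqs >= low_hz & freqs <= high_hz
  xf <- stats::mvfft(t(ts$values))
  xf[!keep, ] <- 0
  ts_with_values(ts, t(Re(stats::mvfft(xf, inverse = TRUE)) / t_n))
}
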