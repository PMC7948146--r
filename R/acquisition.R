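#' Define an acquisition plan
#'
#' Describes a multi-session resting-state acquisition: how many sessions,
#' runs per session and frames per run, the repetition time, the per-unit
#' signal-to-noise variance ratio, and the QC metadata attached to each
#' simulated run. The defaults mirror a dense single-subject protocol:
#' 31 sessions, 2 runs per session, 418 usable frames at TR = 1 s.
#'
#' @param n_sessions Number of sessions (>= 1).
#' @param runs_per_session Runs per session (>= 1).
#' @param frames_per_run Frames per run after equilibration discard.
#' @param tr_seconds Repetition time in seconds.
#' @param snr Signal-to-noise variance ratio s: each unit's series is
#'   \code{sqrt(s) * g + e} with unit-variance latent g and noise e, so
#'   the expected unit-latent correlation is \code{sqrt(s / (s + 1))}.
#'   \code{Inf} gives noiseless series equal to the latent.
#' @param motion_per_run Maximum absolute motion (mm) recorded for each
#'   run; scalar or vector recycled across runs.
#' @param tsnr_per_run Temporal SNR recorded for each run; scalar or
#'   vector recycled across runs.
#' @param latent_band Optional c(low, high) Hz band restricting the
#'   latent network signals (e.g. c(0.01, 0.1), the analyzed band, which
#'   makes band-pass filtering non-destructive). Default NULL: white
#'   latents, which keep the full temporal degrees of freedom. Band
#'   limiting concentrates the latents on few Fourier modes and inflates
#'   chance correlations between networks accordingly.
#' @return An object of class \code{acq_plan}.
#' @export
acquisition_plan <- function(n_sessions = 31, runs_per_session = 2,
                             frames_per_run = 418, tr_seconds = 1,
                             snr = 1, motion_per_run = 0.5,
                             tsnr_per_run = 250,
                             latent_band = NULL) {
  stopifnot(n_sessions >= 1, runs_per_session >= 1, frames_per_run >= 2,
            tr_seconds > 0)
  if (!is.numeric(snr) || snr < 0) stop("snr must be >= 0")
  structure(list(n_sessions = as.integer(n_sessions),
                 runs_per_session = as.integer(runs_per_session),
                 frames_per_run = as.integer(frames_per_run),
                 tr_seconds = tr_seconds, snr = snr,
                 motion_per_run = motion_per_run,
                 tsnr_per_run = tsnr_per_run,
                 latent_band = latent_band),
            class = "acq_plan")
}

# Draw an n x T matrix of unit-variance latent processes: Gaussian white
# noise, optionally band-limited by frequency-domain masking, then
# standardized to empirical mean 0 / sd 1 per row.
draw_latents <- function(n, t, tr, band) {
  x <- matrix(stats::rnorm(n * t), n, t)
  if (!is.null(band)) {
    freqs <- (seq_len(t) - 1) / (t * tr)
    freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
    keep <- freqs >= band[1] & freqs <= band[2]
    if (!any(keep)) stop("latent band contains no Fourier frequency")
    xf <- stats::mvfft(t(x))
    xf[!keep, ] <- 0
    x <- t(Re(stats::mvfft(xf, inverse = TRUE)) / t)
  }
  x <- x - rowMeans(x)
  sdv <- sqrt(rowSums(x^2) / (t - 1))
  x / sdv
}

#' Simulate a multi-session acquisition for a synthetic subject
#'
#' Draws, independently per run, one unit-variance latent time course per
#' (network, cortical hemisphere) — plus body-part latents for the
#' somatomotor network, coupled to the shared somatomotor latent — and
#' builds each unit's series as \code{sqrt(snr) * g + e} where g is the
#' unit's latent and e is unit-variance white noise. Cerebellar voxels
#' follow the latent of their network in the \emph{contralateral}
#' cortical hemisphere, which is the coupling structure the winner-take-
#' all parcellation is designed to recover.
#'
#' @param scene A \code{gt_scene}.
#' @param plan An \code{acq_plan}.
#' @param seed Integer seed; the full session set is deterministic
#'   given it.
#' @param keep_latents Attach each run's latent matrix (one row per
#'   latent process) as element \code{latents}, for calibration checks.
#' @return An object of class \code{session_set}: a list of runs, each
#'   with elements \code{cortex} and \code{cerebellum} (\code{ts_matrix})
#'   and \code{qc} (a \code{run_qc_record}).
#' @export
simulate_session_set <- function(scene, plan = acquisition_plan(),
                                 seed = 1L, keep_latents = FALSE) {
  stopifnot(inherits(scene, "gt_scene"), inherits(plan, "acq_plan"))
  if (plan$snr < 0) stop("snr must be >= 0")
  t <- plan$frames_per_run
  n_runs <- plan$n_sessions * plan$runs_per_session
  motion <- rep_len(plan$motion_per_run, n_runs)
  tsnr <- rep_len(plan$tsnr_per_run, n_runs)
  cortex_latent <- c(scene$cortex_latent_left, scene$cortex_latent_right)
  hemi <- c(rep("left", length(scene$cortex_labels_left)),
            rep("right", length(scene$cortex_labels_right)))
  rho <- scene$body_part_coupling
  runs <- with_seed(seed, {
    out <- vector("list", n_runs)
    ri <- 0L
    for (s in seq_len(plan$n_sessions)) {
      for (r in seq_len(plan$runs_per_session)) {
        ri <- ri + 1L
        lat <- draw_latents(nrow(scene$latents), t, plan$tr_seconds,
                            plan$latent_band)
        child <- which(!is.na(scene$latents$parent))
        if (length(child) > 0L && rho < 1) {
          mixed <- sqrt(rho) * lat[scene$latents$parent[child], , drop = FALSE] +
            sqrt(1 - rho) * lat[child, , drop = FALSE]
          # restandardize: finite-sample parent/unique cross terms would
          # otherwise leave children slightly off unit variance
          mixed <- mixed - rowMeans(mixed)
          lat[child, ] <- mixed / sqrt(rowSums(mixed^2) / (t - 1))
        } else if (length(child) > 0L) {
          lat[child, ] <- lat[scene$latents$parent[child], ]
        }
        make_block <- function(latent_ids) {
          g <- lat[latent_ids, , drop = FALSE]
          if (is.infinite(plan$snr)) return(g)
          sqrt(plan$snr) * g +
            matrix(stats::rnorm(length(latent_ids) * t),
                   length(latent_ids), t)
        }
        run_id <- sprintf("ses%02d_run%d", s, r)
        out[[ri]] <- list(
          cortex = ts_matrix(make_block(cortex_latent),
                             tr_seconds = plan$tr_seconds,
                             unit_space = "cortex", run_id = run_id,
                             session_id = s, hemisphere = hemi),
          cerebellum = ts_matrix(make_block(scene$voxel_latent),
                                 tr_seconds = plan$tr_seconds,
                                 unit_space = "cerebellum_volume",
                                 run_id = run_id, session_id = s),
          qc = run_qc_record(run_id, motion[ri], tsnr[ri]),
          session_id = s, run_id = run_id)
        if (keep_latents) out[[ri]]$latents <- lat
      }
    }
    out
  })
  structure(list(runs = runs, plan = plan, seed = as.integer(seed)),
            class = "session_set")
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("session_set: %d runs over %d sessions (T = %d, snr = %g)\n",
              length(x$runs), x$plan$n_sessions, x$plan$frames_per_run,
              x$plan$snr))
  invisible(x)
}
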