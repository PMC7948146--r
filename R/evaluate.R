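# Extract a per-unit label vector from any parcellation representation.
parc_labels <- function(p) {
  if (inherits(p, "surface_parcellation")) return(p$labels)
  if (inherits(p, "volume_parcellation")) return(as.integer(p$labels[p$mask]))
  as.integer(p)
}

parc_K <- function(p, default = NULL) {
  if (inherits(p, "surface_parcellation") ||
      inherits(p, "volume_parcellation")) return(p$K)
  default %||% max(parc_labels(p))
}

#' Percent agreement between two parcellations
#'
#' The overlap is computed over units that carry a nonzero label in
#' \emph{both} parcellations (and lie inside \code{mask} if given):
#' 100 times the fraction of those units with identical labels. Units
#' unassigned in either parcellation contribute to neither numerator nor
#' denominator.
#'
#' @param a,b Parcellations over the same unit space
#'   (\code{surface_parcellation}, \code{volume_parcellation} or integer
#'   vectors).
#' @param mask Optional logical vector restricting the comparison.
#' @return List with \code{percent_same_label}, \code{n_compared} and a
#'   \code{per_network} agreement table.
#' @export
overlap_percent <- function(a, b, mask = NULL) {
  la <- parc_labels(a)
  lb <- parc_labels(b)
  if (length(la) != length(lb)) stop("parcellations differ in length")
  use <- la > 0L & lb > 0L
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(la))
    use <- use & mask
  }
  if (!any(use)) stop("no jointly labelled units to compare")
  same <- la[use] == lb[use]
  nets <- sort(unique(la[use]))
  per_network <- data.frame(
    network = nets,
    n = vapply(nets, function(n) sum(la[use] == n), integer(1)),
    agree = vapply(nets, function(n) sum(same[la[use] == n]), integer(1)))
  per_network$percent <- 100 * per_network$agree / per_network$n
  list(percent_same_label = 100 * mean(same),
       n_compared = sum(use), per_network = per_network)
}

#' Match arbitrary cluster labels to a reference parcellation
#'
#' Clustering outputs carry arbitrary label identities. This finds the
#' one-to-one label permutation maximizing agreement with a reference
#' (exact assignment-problem solution on the K x K confusion matrix) and
#' returns the relabelled estimate together with post-match accuracy over
#' jointly labelled units.
#'
#' @param estimate,reference Parcellations over the same unit space.
#' @return List with \code{labels} (relabelled estimate), \code{mapping}
#'   (estimate label -> reference label) and \code{accuracy} in [0, 1].
#' @export
match_labels <- function(estimate, reference) {
  le <- parc_labels(estimate)
  lr <- parc_labels(reference)
  if (length(le) != length(lr)) stop("parcellations differ in length")
  use <- le > 0L & lr > 0L
  if (!any(use)) stop("no jointly labelled units")
  K <- max(parc_K(estimate), parc_K(reference))
  conf <- matrix(0, K, K)
  tab <- table(factor(le[use], levels = 1:K),
               factor(lr[use], levels = 1:K))
  conf[] <- as.numeric(tab)
  sol <- assign_labels_max(conf)
  mapping <- sol$assignment
  relab <- le
  relab[le > 0L] <- mapping[le[le > 0L]]
  list(labels = relab, mapping = mapping,
       accuracy = mean(relab[use] == lr[use]))
}

#' Split sessions into discovery and replication halves
#'
#' Odd-numbered sessions (1-based) form the discovery set and even
#' sessions the replication set; runs always follow their session, so a
#' 31-session acquisition splits 16/15.
#'
#' @param sessions A \code{session_set}.
#' @return List of two \code{session_set}s, \code{discovery} and
#'   \code{replication}.
#' @export
split_half_protocol <- function(sessions) {
  stopifnot(inherits(sessions, "session_set"))
  sess <- vapply(sessions$runs, function(r) as.integer(r$session_id),
                 integer(1))
  if (length(unique(sess)) < 2L) stop("need at least 2 sessions to split")
  odd <- sess %% 2L == 1L
  if (!any(odd) || all(odd)) stop("one split half would be empty")
  subset_set <- function(keep) {
    out <- sessions
    out$runs <- sessions$runs[keep]
    out
  }
  list(discovery = subset_set(odd), replication = subset_set(!odd))
}

#' Validate a cerebellar zone by seeding back to the cortex
#'
#' Computes the run-averaged Fisher-z cortical connectivity map of a
#' cerebellar seed and quantifies how specifically it recapitulates a
#' target cortical network: (i) the contrast of mean z inside versus
#' outside the target network, and (ii) the Dice coefficient between the
#' top-m vertices of the map (m = target network size) and the target
#' network itself.
#'
#' @param seed A \code{seed_region} in cerebellar space.
#' @param runs A \code{session_set} or list of runs (typically the
#'   replication half when the seed was picked on the discovery half).
#' @param target Target network id.
#' @param cortex_labels A \code{surface_parcellation} over the cortical
#'   vertices of the runs.
#' @param coords Optional voxel mm-coordinates for sphere seeds.
#' @param target_hemisphere Optional "left"/"right": restrict the target
#'   set to that cortical hemisphere (e.g. the hemisphere contralateral
#'   to the seed), using the runs' vertex hemisphere table.
#' @return List with \code{z_map} (\code{scalar_map}),
#'   \code{specificity} (inside-minus-outside mean z) and \code{dice}.
#' @export
seed_to_cortex_validation <- function(seed, runs, target, cortex_labels,
                                      coords = NULL,
                                      target_hemisphere = NULL) {
  if (inherits(runs, "session_set")) runs <- runs$runs
  stopifnot(length(runs) >= 1L,
            inherits(cortex_labels, "surface_parcellation"))
  lab <- cortex_labels$labels
  inside <- lab == target
  if (!is.null(target_hemisphere)) {
    hemi <- runs[[1]]$cortex$hemisphere
    if (is.null(hemi)) stop("runs carry no vertex hemisphere table")
    inside <- inside & hemi == target_hemisphere
  }
  if (!any(inside)) stop("target network absent from cortex labels")
  zmaps <- lapply(runs, function(r) {
    tc <- seed_timecourse(r$cerebellum, seed, coords = coords)
    fisher_z(correlation_map(r$cortex, tc))
  })
  zbar <- average_maps(zmaps)
  labelled <- lab > 0L
  spec <- mean(zbar$values[inside]) -
    mean(zbar$values[labelled & !inside])
  m <- sum(inside)
  top <- top_k_indices(zbar$values, m)
  dice <- 2 * sum(inside[top]) / (m + m)
  list(z_map = zbar, specificity = spec, dice = dice)
}

#' Per-network composition of a parcellation
#'
#' Fraction of labelled units assigned to each network; unassigned
#' (label 0) units are excluded, so fractions sum to 1.
#'
#' @param parcellation Any parcellation representation.
#' @param mask Optional logical vector restricting the units (e.g. one
#'   hemisphere).
#' @param K Number of networks (inferred if the parcellation carries it).
#' @return Named numeric vector of length K summing to 1.
#' @export
network_composition <- function(parcellation, mask = NULL, K = NULL) {
  lab <- parc_labels(parcellation)
  if (!is.null(mask)) {
    stopifnot(length(mask) == length(lab))
    lab <- lab[mask]
  }
  lab <- lab[lab > 0L]
  if (length(lab) == 0L) stop("no labelled units")
  K <- K %||% parc_K(parcellation)
  counts <- tabulate(lab, nbins = K)
  stats::setNames(counts / sum(counts), paste0("net", seq_len(K)))
}

# r, slope and intercept of y ~ x with a degeneracy flag instead of NaN.
fraction_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
  if (degenerate) {
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                degenerate = TRUE))
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = stats::cor(x, y), slope = fit$coefficients[[2]],
       intercept = fit$coefficients[[1]], degenerate = FALSE)
}

#' Cortex-cerebellum proportionality of network extents
#'
#' Compares the fraction of cortical surface occupied by each network
#' with the fraction of cerebellar volume assigned to the same network in
#' the \emph{contralateral} hemisphere: Pearson r and the least-squares
#' line, separately per cerebellar hemisphere. Fractions and percentages
#' give identical r. A constant fraction vector on either axis is
#' reported as degenerate rather than propagating NaN.
#'
#' @param cortex Either a plain numeric fraction vector, or a list with
#'   elements \code{left} and \code{right} (per cortical hemisphere).
#' @param cerebellum Same shape as \code{cortex}, for the cerebellum.
#' @return An object of class \code{proportionality_report}: one entry
#'   per cerebellar hemisphere (or \code{both} for plain vectors) with
#'   r, slope, intercept, a degeneracy flag and the paired fractions.
#' @export
proportionality <- function(cortex, cerebellum) {
  pair <- function(x, y, label) {
    stopifnot(length(x) == length(y))
    if (length(x) < 3L) stop("need at least 3 networks")
    if (abs(sum(x) - 1) > 1e-6 || abs(sum(y) - 1) > 1e-6) {
      stop("fractions must sum to 1 on each side")
    }
    c(list(hemisphere = label,
           pairs = data.frame(network = seq_along(x),
                              cortex_fraction = as.numeric(x),
                              cerebellum_fraction = as.numeric(y))),
      fraction_regression(as.numeric(x), as.numeric(y)))
  }
  out <- if (is.list(cortex)) {
    stopifnot(is.list(cerebellum),
              all(c("left", "right") %in% names(cortex)),
              all(c("left", "right") %in% names(cerebellum)))
    list(left = pair(cortex$right, cerebellum$left, "left"),
         right = pair(cortex$left, cerebellum$right, "right"))
  } else {
    list(both = pair(cortex, cerebellum, "both"))
  }
  structure(out, class = "proportionality_report")
}

#' @export
print.proportionality_report <- function(x, ...) {
  cat("Cortex-cerebellum proportionality\n")
  for (side in names(x)) {
    e <- x[[side]]
    if (e$degenerate) {
      cat(sprintf("  %s cerebellum: degenerate (constant fractions)\n",
                  side))
    } else {
      cat(sprintf("  %s cerebellum: r = %.3f, slope = %.3f, intercept = %.3f (%d networks)\n",
                  side, e$r, e$slope, e$intercept, nrow(e$pairs)))
    }
  }
  invisible(x)
}
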