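#' Default 10-network catalogue
#'
#' Names follow the conventional resting-state network nomenclature at the
#' 10-network resolution, with a distinct language network and two
#' juxtaposed default networks.
#'
#' @return Character vector of network names.
#' @export
default_networks <- function() {
  c("Somatomotor", "Visual", "DorsalAttention", "SalVenAttention",
    "ControlA", "ControlB", "DefaultA", "DefaultB", "Language", "Limbic")
}

# Largest-remainder apportionment of n units over fractions, each class
# guaranteed at least one unit when n >= length(fractions).
apportion <- function(n, fractions) {
  k <- length(fractions)
  f <- fractions / sum(fractions)
  counts <- floor(n * f)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac_part <- n * f - counts
    bump <- order(-frac_part, seq_len(k))[seq_len(rem)]
    counts[bump] <- counts[bump] + 1L
  }
  if (n >= k && any(counts == 0L)) {
    for (j in which(counts == 0L)) {
      donor <- which.max(counts)
      counts[donor] <- counts[donor] - 1L
      counts[j] <- 1L
    }
  }
  as.integer(counts)
}

# Per-hemisphere network fractions from base fractions and a per-network
# left/right extent ratio (lateralization > 1 means more leftward extent).
hemisphere_fractions <- function(base, lateralization) {
  left <- base * 2 * lateralization / (1 + lateralization)
  right <- base * 2 / (1 + lateralization)
  cbind(left = left / sum(left), right = right / sum(right))
}

#' Build a ground-truth synthetic subject
#'
#' Constructs a synthetic "subject": cortical network labels on two
#' hemispheres of surface vertices, and cerebellar network labels on a
#' 3-D voxel grid. The cerebellar layout encodes the topographic structure
#' assumed by the downstream analysis:
#' \itemize{
#'   \item each cerebellar hemisphere holds three representations
#'     (strata) of the full cortical network set, laid out along the
#'     anterior-posterior (y) axis, with the network order of the second
#'     stratum mirrored relative to the first;
#'   \item a cerebellar voxel is driven by the latent signal of its
#'     network in the \emph{contralateral} cortical hemisphere;
#'   \item somatomotor territory is subdivided into foot, hand and tongue
#'     bands (ordered foot-hand-tongue along y in stratum 1 and reversed
#'     in stratum 2), with an unlabeled gap between foot and hand;
#'   \item one network (by default the language network) is lateralized:
#'     it occupies more left-cortical than right-cortical territory, and
#'     correspondingly more right- than left-cerebellar territory.
#' }
#'
#' The grid is an integer lattice with 2-mm spacing in an MNI-like frame
#' centred on x = 0; voxels with centre x < 0 belong to the left
#' hemisphere. Voxel centres are at \code{origin + spacing * (index - 1)}
#' with 1-based array indices.
#'
#' @param n_networks Number of networks K (default 10).
#' @param vertices_per_hemisphere Cortical vertices per hemisphere.
#' @param grid_dim Integer length-3 voxel grid dimensions.
#' @param spacing_mm Isotropic voxel size in mm.
#' @param mask_margin Voxels of empty border kept outside the cerebellar
#'   mask on every face of the grid.
#' @param network_fractions Base fraction of units per network (length K,
#'   normalized internally). Defaults to a decreasing profile so network
#'   sizes vary, as they do in real cortex.
#' @param lateralization Per-network left/right extent ratio (length K).
#'   Default 1 for all networks except the language network (1.3).
#' @param network_names Optional character vector of length K.
#' @param somatomotor Index of the somatomotor network (body-part bands).
#' @param language Index of the lateralized language-like network.
#' @param body_part_fractions Fractions of the somatomotor cerebellar
#'   block given to foot, gap, hand, tongue (in y order for stratum 1).
#' @param body_part_coupling Squared correlation between a body-part
#'   latent and the shared somatomotor network latent, in [0, 1].
#' @param n_strata Number of cerebellar representations per hemisphere.
#' @param seed Integer seed; the construction is deterministic given it.
#'
#' @return An object of class \code{gt_scene}.
#' @export
build_scene <- function(n_networks = 10,
                        vertices_per_hemisphere = 2000,
                        grid_dim = c(14L, 17L, 8L),
                        spacing_mm = 2,
                        mask_margin = 1L,
                        network_fractions = NULL,
                        lateralization = NULL,
                        network_names = NULL,
                        somatomotor = 1L,
                        language = 9L,
                        body_part_fractions = c(foot = 0.3, gap = 0.1,
                                                hand = 0.3, tongue = 0.3),
                        body_part_coupling = 0.8,
                        n_strata = 3L,
                        seed = 1L) {
  K <- as.integer(n_networks)
  if (K < 2L) stop("need at least 2 networks")
  V <- as.integer(vertices_per_hemisphere)
  if (V < K) stop("need at least K vertices per hemisphere")
  grid_dim <- as.integer(grid_dim)
  stopifnot(length(grid_dim) == 3L, all(grid_dim >= 3L))
  if (is.null(network_fractions)) {
    # realistic moderate spread of network sizes (13% down to 7% at K = 10)
    network_fractions <- seq(1.3, 0.7, length.out = K)
  }
  stopifnot(length(network_fractions) == K, all(network_fractions > 0))
  network_fractions <- network_fractions / sum(network_fractions)
  if (is.null(lateralization)) {
    lateralization <- rep(1, K)
    if (language >= 1L && language <= K) lateralization[language] <- 1.3
  }
  stopifnot(length(lateralization) == K, all(lateralization > 0))
  if (is.null(network_names)) {
    network_names <- if (K == 10L) default_networks() else
      paste0("Network", seq_len(K))
  }
  stopifnot(length(network_names) == K)
  if (body_part_coupling < 0 || body_part_coupling > 1) {
    stop("body_part_coupling must be in [0, 1]")
  }
  hemi_frac <- hemisphere_fractions(network_fractions, lateralization)

  # --- cortex: contiguous blocks per hemisphere, foot/hand/tongue thirds
  #     within the somatomotor block ---
  lay_cortex <- function(hemi) {
    counts <- apportion(V, hemi_frac[, hemi])
    labels <- rep.int(seq_len(K), counts)
    body <- rep("none", V)
    som <- which(labels == somatomotor)
    if (length(som) >= 3L) {
      thirds <- apportion(length(som), c(1, 1, 1))
      body[som] <- rep.int(c("foot", "hand", "tongue"), thirds)
    }
    list(labels = labels, body = body)
  }
  cl <- lay_cortex("left")
  cr <- lay_cortex("right")

  # --- cerebellum: box mask inside a margin; strata along y ---
  origin <- -spacing_mm * (grid_dim - 1) / 2
  mask <- array(FALSE, grid_dim)
  m <- mask_margin
  mask[(1 + m):(grid_dim[1] - m),
       (1 + m):(grid_dim[2] - m),
       (1 + m):(grid_dim[3] - m)] <- TRUE
  idx <- which(mask, arr.ind = TRUE)
  coords <- sweep((idx - 1) * spacing_mm, 2, origin, `+`)
  colnames(coords) <- c("x", "y", "z")
  voxel_hemi <- ifelse(coords[, "x"] < 0, "left", "right")

  labels_vec <- integer(nrow(idx))
  rep_index <- integer(nrow(idx))
  body_vox <- rep("none", nrow(idx))
  y_levels <- sort(unique(coords[, "y"]))
  strata_of_y <- apportion(length(y_levels), rep(1, n_strata))
  y_stratum <- rep.int(seq_len(n_strata), strata_of_y)

  for (hemi in c("left", "right")) {
    contra <- if (hemi == "left") "right" else "left"
    frac <- hemi_frac[, contra]  # cerebellar extent mirrors contralateral cortex
    for (s in seq_len(n_strata)) {
      in_stratum <- voxel_hemi == hemi &
        y_stratum[match(coords[, "y"], y_levels)] == s
      vox <- which(in_stratum)
      if (length(vox) < K) {
        stop(sprintf(
          "infeasible layout: stratum %d of %s hemisphere has %d voxels for %d networks",
          s, hemi, length(vox), K))
      }
      ord <- vox[order(coords[vox, "y"], coords[vox, "x"], coords[vox, "z"])]
      net_order <- if (s == 2L) rev(seq_len(K)) else seq_len(K)
      counts <- apportion(length(ord), frac[net_order])
      labels_vec[ord] <- rep.int(net_order, counts)
      rep_index[ord] <- s
      som_vox <- ord[labels_vec[ord] == somatomotor]
      if (length(som_vox) >= 4L) {
        bp_names <- names(body_part_fractions)
        bp_order <- if (s == 2L) rev(seq_along(bp_names)) else
          seq_along(bp_names)
        bp_counts <- apportion(length(som_vox),
                               body_part_fractions[bp_order])
        bp <- rep.int(bp_names[bp_order], bp_counts)
        body_vox[som_vox] <- ifelse(bp == "gap", "none", bp)
      }
    }
  }
  cerebellum_labels <- array(0L, grid_dim)
  cerebellum_labels[mask] <- labels_vec

  # --- latent catalogue: one parent latent per (network, cortical
  #     hemisphere); somatomotor adds per-body-part child latents coupled
  #     to the parent with correlation sqrt(body_part_coupling) ---
  latents <- expand.grid(network = seq_len(K),
                         cortex_hemisphere = c("left", "right"),
                         body_part = "none",
                         stringsAsFactors = FALSE)
  latents$parent <- NA_integer_
  for (h in c("left", "right")) {
    for (bp in c("foot", "hand", "tongue")) {
      latents <- rbind(latents, data.frame(
        network = somatomotor, cortex_hemisphere = h, body_part = bp,
        parent = which(latents$network == somatomotor &
                         latents$cortex_hemisphere == h &
                         latents$body_part == "none")))
    }
  }
  latent_id <- function(network, cortex_hemisphere, body_part) {
    hit <- which(latents$network == network &
                   latents$cortex_hemisphere == cortex_hemisphere &
                   latents$body_part == body_part)
    if (length(hit) == 0L) {  # body part without its own latent
      hit <- which(latents$network == network &
                     latents$cortex_hemisphere == cortex_hemisphere &
                     latents$body_part == "none")
    }
    hit[1L]
  }
  cortex_latent <- function(labels, body, hemi) {
    mapply(latent_id, labels, hemi, body)
  }
  scene <- structure(list(
    n_networks = K,
    network_names = network_names,
    cortex_labels_left = cl$labels,
    cortex_labels_right = cr$labels,
    cortex_body_left = cl$body,
    cortex_body_right = cr$body,
    cerebellum_labels = cerebellum_labels,
    cerebellum_mask = mask,
    grid_dim = grid_dim,
    spacing_mm = spacing_mm,
    origin_mm = origin,
    voxel_index = idx,
    voxel_coords = coords,
    hemisphere_of_voxel = voxel_hemi,
    representation_index = rep_index,
    body_part = body_vox,
    network_fractions = hemi_frac,
    lateralization = lateralization,
    somatomotor = as.integer(somatomotor),
    language = as.integer(language),
    body_part_coupling = body_part_coupling,
    latents = latents,
    rng_seed = as.integer(seed)
  ), class = "gt_scene")
  scene$cortex_latent_left <- cortex_latent(cl$labels, cl$body, "left")
  scene$cortex_latent_right <- cortex_latent(cr$labels, cr$body, "right")
  # contralaterality: a voxel follows its network's latent in the
  # opposite cortical hemisphere
  contra <- ifelse(voxel_hemi == "left", "right", "left")
  scene$voxel_latent <- mapply(latent_id, labels_vec, contra, body_vox)
  scene
}

#' @export
print.gt_scene <- function(x, ...) {
  cat("Ground-truth cerebro-cerebellar scene\n")
  cat(sprintf("  networks: %d (%s, ...)\n", x$n_networks,
              paste(utils::head(x$network_names, 3), collapse = ", ")))
  cat(sprintf("  cortex: %d + %d vertices (L + R)\n",
              length(x$cortex_labels_left), length(x$cortex_labels_right)))
  cat(sprintf("  cerebellum: %d in-mask voxels on a %s grid (%g mm)\n",
              sum(x$cerebellum_mask),
              paste(x$grid_dim, collapse = "x"), x$spacing_mm))
  cat(sprintf("  representations per hemisphere: %d\n",
              max(x$representation_index)))
  invisible(x)
}

# 6-connected neighbours of in-mask voxels, as an adjacency list over
# in-mask voxel indices (positions in scene$voxel_index).
voxel_neighbours <- function(scene) {
  idx <- scene$voxel_index
  key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3])
  lookup <- new.env(hash = TRUE, size = nrow(idx))
  ks <- key(idx)
  for (i in seq_len(nrow(idx))) assign(ks[i], i, envir = lookup)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  lapply(seq_len(nrow(idx)), function(i) {
    nb <- integer(0)
    for (o in seq_len(6)) {
      k <- paste(idx[i, 1] + offs[o, 1], idx[i, 2] + offs[o, 2],
                 idx[i, 3] + offs[o, 3])
      hit <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(hit)) nb <- c(nb, hit)
    }
    nb
  })
}

# Iteratively flip boundary labels until ~`target` units differ from the
# original labelling. `neighbours` is an adjacency list.
erode_labels <- function(labels, neighbours, target) {
  orig <- labels
  n <- length(labels)
  changed <- 0L
  repeat {
    if (changed >= target) break
    cand <- which(vapply(seq_len(n), function(i) {
      labels[i] == orig[i] &&
        any(labels[neighbours[[i]]] != labels[i])
    }, logical(1)))
    if (length(cand) == 0L) break
    take <- sample(cand, min(length(cand), target - changed))
    for (i in take) {
      diffnb <- neighbours[[i]][labels[neighbours[[i]]] != labels[i]]
      if (length(diffnb) > 0L) {
        labels[i] <- labels[diffnb[sample.int(length(diffnb), 1L)]]
        changed <- changed + 1L
      }
    }
  }
  labels
}

#' Perturb a subject's network topography
#'
#' Models between-subject idiosyncrasy by reassigning boundary-adjacent
#' units (cortical vertices and cerebellar voxels) to a neighbouring
#' network until approximately \code{magnitude} of all units differ from
#' the source scene. Label overlap with the original therefore decreases
#' roughly linearly in \code{magnitude}; magnitude 0 returns an identical
#' scene.
#'
#' @param scene A \code{gt_scene}.
#' @param magnitude Fraction of units to reassign, in [0, 1].
#' @param seed Integer seed; deterministic given it.
#' @return A perturbed \code{gt_scene}.
#' @export
perturb_subject <- function(scene, magnitude, seed = 1L) {
  stopifnot(inherits(scene, "gt_scene"))
  if (!is.numeric(magnitude) || magnitude < 0 || magnitude > 1) {
    stop("magnitude must be in [0, 1]")
  }
  if (magnitude == 0) return(scene)
  with_seed(seed, {
    out <- scene
    # cortex: 1-D index adjacency within hemisphere
    for (hemi in c("left", "right")) {
      fld <- paste0("cortex_labels_", hemi)
      labs <- scene[[fld]]
      n <- length(labs)
      nb <- lapply(seq_len(n), function(i) {
        c(if (i > 1L) i - 1L, if (i < n) i + 1L)
      })
      new <- erode_labels(labs, nb, round(magnitude * n))
      moved <- new != labs
      out[[fld]] <- new
      bfld <- paste0("cortex_body_", hemi)
      out[[bfld]][moved] <- "none"
      lfld <- paste0("cortex_latent_", hemi)
      parent <- which(scene$latents$body_part == "none" &
                        scene$latents$cortex_hemisphere == hemi)
      out[[lfld]][moved] <- parent[match(new[moved],
                                         scene$latents$network[parent])]
    }
    # cerebellum: 6-connected grid adjacency
    nb <- voxel_neighbours(scene)
    labs <- scene$cerebellum_labels[scene$cerebellum_mask]
    new <- erode_labels(labs, nb, round(magnitude * length(labs)))
    moved <- new != labs
    out$cerebellum_labels[scene$cerebellum_mask] <- new
    out$body_part[moved] <- "none"
    contra <- ifelse(scene$hemisphere_of_voxel == "left", "right", "left")
    for (h in c("left", "right")) {
      parent <- which(scene$latents$body_part == "none" &
                        scene$latents$cortex_hemisphere == h)
      sel <- moved & contra == h
      out$voxel_latent[sel] <- parent[match(new[sel],
                                            scene$latents$network[parent])]
    }
    out$rng_seed <- as.integer(seed)
    out
  })
}
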