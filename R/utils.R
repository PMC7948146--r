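# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so seeded operations never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Row-standardize a units x timepoints matrix to mean 0, sd 1 per row.
# Zero-variance rows come back as all-zero with attribute "degenerate"
# marking them, so correlations against them evaluate to 0 not NaN.
row_standardize <- function(x) {
  mu <- rowMeans(x)
  xc <- x - mu
  ss <- sqrt(rowSums(xc^2))
  degen <- ss <= .Machine$double.eps * ncol(x)
  ss[degen] <- 1
  out <- xc / ss
  out[degen, ] <- 0
  attr(out, "degenerate") <- degen
  out
}

# Pearson correlation of every row of `a` against every row of `b`
# (rows are units, columns timepoints). Zero-variance rows give r = 0.
row_cor <- function(a, b) {
  sa <- row_standardize(a)
  sb <- row_standardize(b)
  r <- tcrossprod(sa, sb)
  # numerical guard: |r| can exceed 1 by ~1e-15
  r[r > 1] <- 1
  r[r < -1] <- -1
  attr(r, "degenerate_rows") <- attr(sa, "degenerate")
  attr(r, "degenerate_cols") <- attr(sb, "degenerate")
  r
}

# Exact solution of the K x K assignment problem (maximize sum of
# score[i, perm[i]]) by dynamic programming over column subsets.
# K <= 20 or so; here K is the network count (typically 10).
assign_labels_max <- function(score) {
  k <- nrow(score)
  stopifnot(ncol(score) == k)
  if (k > 20L) stop("assignment solver supports at most 20 labels")
  nstates <- bitwShiftL(1L, k)
  best <- rep(-Inf, nstates)
  choice <- matrix(0L, nstates, 1L)
  best[1L] <- 0
  prev <- vector("list", nstates)
  for (mask in 0L:(nstates - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    i <- sum(bitwAnd(bitwShiftR(mask, 0L:(k - 1L)), 1L)) + 1L  # next row
    if (i > k) next
    for (j in 1L:k) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      nxt <- bitwOr(mask, bit)
      cand <- best[mask + 1L] + score[i, j]
      if (cand > best[nxt + 1L]) {
        best[nxt + 1L] <- cand
        prev[[nxt + 1L]] <- c(mask, j)
      }
    }
  }
  perm <- integer(k)
  mask <- nstates - 1L
  while (mask > 0L) {
    pj <- prev[[mask + 1L]]
    i <- sum(bitwAnd(bitwShiftR(pj[1L], 0L:(k - 1L)), 1L)) + 1L
    perm[i] <- pj[2L]
    mask <- pj[1L]
  }
  list(assignment = perm, value = best[nstates])
}

# Indices of the k largest values; ties at the cutoff broken by lower index.
top_k_indices <- function(x, k) {
  ord <- order(-x, seq_along(x))
  ord[seq_len(k)]
}

# Mode of positive integer labels with deterministic tie handling:
# ties broken by larger summed weight, then by smaller label index.
# Returns c(label, count).
label_mode <- function(labels, weights, n_labels) {
  votes <- tabulate(labels, nbins = n_labels)
  top <- max(votes)
  tied <- which(votes == top)
  if (length(tied) > 1L) {
    sums <- vapply(tied, function(l) sum(weights[labels == l]), numeric(1))
    tied <- tied[sums == max(sums)]
  }
  c(tied[1L], top)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
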