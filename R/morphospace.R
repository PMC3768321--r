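# Morphospace: phylomorphospace nodes and spatial point-pattern analysis --

#' Ancestral coordinates in morphospace
#'
#' Per-axis Brownian-motion maximum-likelihood estimates of internal node
#' positions on a dated tree (via [phytools::fastAnc]); tips keep their
#' observed ordination scores. Together with the tree this defines the
#' phylomorphospace.
#'
#' @param tree Rooted `phylo` with branch durations.
#' @param ord A [pco()] object, or a score matrix with taxon rownames.
#' @param axes Which axes to use (default first three).
#' @param epsilon Added to zero-duration branches (with a warning) so the
#'   BM likelihood is defined.
#' @return Numeric matrix of coordinates with one row per tip and internal
#'   node; tip rows are labelled by taxon, internal rows `node_<id>` using
#'   `ape` node numbering.
#' @export
ancestral_coordinates <- function(tree, ord, axes = 1:3, epsilon = 1e-6) {
  scores <- if (inherits(ord, "pco")) ord$scores else as.matrix(ord)
  if (!all(tree$tip.label %in% rownames(scores)))
    stop("tree tips must all be present in the ordination", call. = FALSE)
  axes <- axes[axes <= ncol(scores)]
  if (any(tree$edge.length == 0)) {
    warning(sprintf("adding epsilon = %g to %d zero-duration branches",
                    epsilon, sum(tree$edge.length == 0)))
    tree$edge.length[tree$edge.length == 0] <- epsilon
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  out <- matrix(NA_real_, ntip + nnode, length(axes))
  colnames(out) <- colnames(scores)[axes]
  rownames(out) <- c(tree$tip.label, paste0("node_", ntip + seq_len(nnode)))
  for (i in seq_along(axes)) {
    x <- scores[tree$tip.label, axes[i]]
    names(x) <- tree$tip.label
    anc <- phytools::fastAnc(tree, x)
    out[seq_len(ntip), i] <- x
    out[ntip + seq_len(nnode), i] <- as.numeric(anc)
  }
  out
}

# Axis-aligned bounding box of a point cloud, expanded by `expand` per side.
observation_box <- function(points, expand = 0.05) {
  rng <- apply(points, 2, range)
  span <- rng[2, ] - rng[1, ]
  rbind(lo = rng[1, ] - expand * span, hi = rng[2, ] + expand * span)
}

#' Ripley's K function in three dimensions
#'
#' Second-order point-pattern statistic for a 3-D point cloud inside an
#' axis-aligned observation box:
#' `K(r) = V / (n (n - 1)) * sum_{i != j} e_ij * 1{d_ij <= r}` with `V`
#' the box volume and `e_ij` the translation edge-correction weight
#' (`V / prod(L_a - |dx_a|)`), or 1 when `correction = "none"`. Values
#' above the CSR expectation `4/3 pi r^3` indicate clustering at scale `r`.
#'
#' @param points n x 3 coordinate matrix.
#' @param r_grid Increasing distances at which to evaluate K; default 100
#'   points from 0 to half the shortest box edge.
#' @param correction `"translation"` (default) or `"none"`.
#' @param box 2 x 3 matrix (rows `lo`, `hi`); default the bounding box of
#'   `points` expanded 5% per side.
#' @param expand Expansion fraction for the default box.
#' @return Object of class `ripley_k`: list with `r`, `k_obs`, `k_theo`,
#'   `n_points`, `box`, `correction`.
#' @export
ripley_k_3d <- function(points, r_grid = NULL,
                        correction = c("translation", "none"),
                        box = NULL, expand = 0.05) {
  correction <- match.arg(correction)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must have three columns", call. = FALSE)
  n <- nrow(points)
  if (n < 2) stop("need at least two points", call. = FALSE)
  if (is.null(box)) box <- observation_box(points, expand)
  L <- box[2, ] - box[1, ]
  if (any(L <= 0)) stop("degenerate observation box (zero extent)", call. = FALSE)
  if (any(t(points) < box[1, ] - 1e-9) || any(t(points) > box[2, ] + 1e-9))
    stop("box must enclose all points", call. = FALSE)
  if (is.null(r_grid)) r_grid <- seq(0, min(L) / 2, length.out = 100)
  if (is.unsorted(r_grid)) stop("r_grid must be increasing", call. = FALSE)
  V <- prod(L)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dx <- abs(points[ij[, 1], , drop = FALSE] - points[ij[, 2], , drop = FALSE])
  dist_ij <- sqrt(rowSums(dx^2))
  w <- if (correction == "translation") {
    V / ((L[1] - dx[, 1]) * (L[2] - dx[, 2]) * (L[3] - dx[, 3]))
  } else rep(1, nrow(dx))
  ord <- order(dist_ij)
  cum_w <- cumsum(w[ord])
  idx <- findInterval(r_grid, dist_ij[ord])
  k_obs <- 2 * c(0, cum_w)[idx + 1] * V / (n * (n - 1))
  structure(list(r = r_grid, k_obs = k_obs, k_theo = 4 / 3 * pi * r_grid^3,
                 n_points = n, box = box, correction = correction),
            class = "ripley_k")
}

#' Monte Carlo envelope for Ripley's K under CSR
#'
#' Simulates `nsim` uniform (complete spatial randomness) patterns of `n`
#' points in the box and returns the pointwise rank-1 (min/max) envelope of
#' their K functions.
#'
#' @param n Number of points per simulated pattern.
#' @param box 2 x 3 observation box.
#' @param r_grid Distances at which K is evaluated.
#' @param nsim Number of simulations (default 999).
#' @param seed Optional RNG seed (local to the call).
#' @param correction Edge correction passed to [ripley_k_3d()].
#' @return List with `lo`, `hi` (pointwise bounds), `r`, `nsim`.
#' @export
csr_envelope <- function(n, box, r_grid, nsim = 999, seed = NULL,
                         correction = "translation") {
  if (nsim < 1) stop("nsim must be >= 1", call. = FALSE)
  L <- box[2, ] - box[1, ]
  ks <- with_seed(seed, {
    vapply(seq_len(nsim), function(s) {
      pts <- cbind(stats::runif(n, box[1, 1], box[2, 1]),
                   stats::runif(n, box[1, 2], box[2, 2]),
                   stats::runif(n, box[1, 3], box[2, 3]))
      ripley_k_3d(pts, r_grid = r_grid, correction = correction, box = box)$k_obs
    }, numeric(length(r_grid)))
  })
  ks <- matrix(ks, nrow = length(r_grid))
  list(r = r_grid, lo = apply(ks, 1, min), hi = apply(ks, 1, max), nsim = nsim)
}

#' Spatial clustering test for taxa in morphospace
#'
#' Runs [ripley_k_3d()] on the taxa in the space of the given ordination
#' axes and compares it with a CSR Monte Carlo envelope; the point pattern
#' is called clustered where the observed K exceeds the envelope.
#'
#' @param ord A [pco()] object or score matrix.
#' @param axes Axes defining the space (default 1:3).
#' @param nsim Envelope simulations (default 999).
#' @param seed Optional RNG seed.
#' @param correction Edge correction.
#' @param expand Box expansion fraction.
#' @return List with the `ripley_k` object `k`, envelope `envelope`, and
#'   logical `clustered` (TRUE if `k_obs` exceeds the upper envelope at any
#'   distance).
#' @export
morphospace_clustering <- function(ord, axes = 1:3, nsim = 999, seed = NULL,
                                   correction = "translation", expand = 0.05) {
  scores <- if (inherits(ord, "pco")) ord$scores else as.matrix(ord)
  pts <- scores[, axes, drop = FALSE]
  k <- ripley_k_3d(pts, correction = correction, expand = expand)
  env <- csr_envelope(nrow(pts), k$box, k$r, nsim = nsim, seed = seed,
                      correction = correction)
  list(k = k, envelope = env,
       clustered = any(k$k_obs > env$hi + 1e-12),
       dispersed = any(k$k_obs < env$lo - 1e-12))
}
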