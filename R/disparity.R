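# Disparity indices, bootstrap profiles, time binning ---------------------

#' Four disparity indices from ordination scores
#'
#' Sum of ranges and root-product of ranges (morphospace occupation), and
#' sum of variances and root-product of variances (dispersal about the
#' group centroid). Root-products use the k-th root (geometric mean of the
#' per-axis values), computed in log space; a zero range or variance on any
#' axis makes the corresponding root-product 0. A single taxon has all
#' indices 0; variances use denominator m - 1.
#'
#' @param scores m x k matrix of axis scores for the taxon set.
#' @return Named numeric vector: `sum_ranges`, `root_prod_ranges`,
#'   `sum_variances`, `root_prod_variances`.
#' @export
disparity_indices <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 1 || ncol(scores) < 1)
    stop("empty score set", call. = FALSE)
  rootprod <- function(v) {
    if (any(v <= 0)) 0 else exp(mean(log(v)))
  }
  if (nrow(scores) == 1) {
    ranges <- rep(0, ncol(scores))
    vars <- rep(0, ncol(scores))
  } else {
    ranges <- apply(scores, 2, function(x) diff(range(x)))
    vars <- apply(scores, 2, stats::var)
  }
  c(sum_ranges = sum(ranges),
    root_prod_ranges = rootprod(ranges),
    sum_variances = sum(vars),
    root_prod_variances = rootprod(vars))
}

#' Bootstrap disparity profile
#'
#' Bootstrap resampling (with replacement) of the taxon set, optionally
#' rarefied to a smaller sample size, giving the mean and percentile 95%
#' CI of each disparity index across replicates.
#'
#' @param scores m x k score matrix.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param rarefy_to Resample size; `NULL` (default) uses the full m.
#' @param seed Optional RNG seed (local to the call).
#' @param group Optional group label recorded in the output.
#' @return A `data.frame` of class `disparity_profile` with one row per
#'   index: `group`, `index`, `n`, `mean`, `ci_lo`, `ci_hi`, `rarefied`,
#'   `rarefaction_n`.
#' @export
bootstrap_disparity <- function(scores, n_reps = 1000, rarefy_to = NULL,
                                seed = NULL, group = NA_character_) {
  scores <- as.matrix(scores)
  m <- nrow(scores)
  if (m < 1) stop("empty score set", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  size <- rarefy_to %||% m
  if (size > m) stop("rarefy_to must be <= number of taxa", call. = FALSE)
  if (size < 2) warning("rarefy_to < 2: variance indices are degenerate")
  reps <- with_seed(seed, {
    vapply(seq_len(n_reps), function(i) {
      disparity_indices(scores[sample.int(m, size, replace = TRUE), , drop = FALSE])
    }, numeric(4))
  })
  reps <- matrix(reps, nrow = 4,
                 dimnames = list(c("sum_ranges", "root_prod_ranges",
                                   "sum_variances", "root_prod_variances"), NULL))
  out <- data.frame(
    group = group,
    index = rownames(reps),
    n = m,
    mean = rowMeans(reps),
    ci_lo = apply(reps, 1, stats::quantile, 0.025),
    ci_hi = apply(reps, 1, stats::quantile, 0.975),
    rarefied = !is.null(rarefy_to),
    rarefaction_n = size,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("disparity_profile", "data.frame")
  out
}

#' Assign taxa to time bins
#'
#' A taxon belongs to a bin when its observed range `[lad, fad]` overlaps
#' the bin's age interval `[end, start)`, closed on the FAD side (a taxon
#' whose FAD equals a bin's younger edge joins the older bin). Taxa whose
#' ranges fall outside all bins are excluded and reported via the
#' `excluded` attribute.
#'
#' @param ranges Range table (`taxon`, `fad`, `lad`), e.g. [read_ranges()].
#' @param bins A [time_bins()] table.
#' @return Named list (one element per bin label) of taxon character
#'   vectors, with attribute `excluded`.
#' @export
bin_taxa <- function(ranges, bins) {
  ranges <- validate_ranges(ranges)
  if (nrow(ranges) == 0) stop("empty range table", call. = FALSE)
  member <- lapply(seq_len(nrow(bins)), function(b) {
    hit <- ranges$fad >= bins$end[b] & ranges$lad < bins$start[b]
    ranges$taxon[hit]
  })
  names(member) <- bins$label
  excluded <- setdiff(ranges$taxon, unique(unlist(member)))
  attr(member, "excluded") <- excluded
  member
}

#' Significance by confidence-interval non-overlap
#'
#' Two disparity estimates are called significantly different when their
#' 95% CIs are disjoint.
#'
#' @param ci1,ci2 Length-2 numeric vectors `(lo, hi)`.
#' @return Logical.
#' @export
ci_significance <- function(ci1, ci2) {
  ci1[2] < ci2[1] || ci2[2] < ci1[1]
}

#' Disparity profiles by group
#'
#' Unrarefied and rarefied (to the smallest group) bootstrap disparity
#' for each taxon group.
#'
#' @param ord A [pco()] object or score matrix.
#' @param groups Named character/factor vector mapping taxon label to
#'   group, or a named list of taxon vectors.
#' @param n_reps Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @return A `disparity_profile` data frame with unrarefied and rarefied
#'   rows for every group.
#' @export
disparity_by_group <- function(ord, groups, n_reps = 1000, seed = NULL) {
  scores <- if (inherits(ord, "pco")) ord$scores else as.matrix(ord)
  sets <- groups_as_list(groups)
  miss <- setdiff(unlist(sets), rownames(scores))
  if (length(miss) > 0)
    stop(sprintf("taxa not in ordination: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  n_min <- min(lengths(sets))
  out <- lapply(seq_along(sets), function(i) {
    s <- scores[sets[[i]], , drop = FALSE]
    rbind(
      bootstrap_disparity(s, n_reps, seed = seed_offset(seed, 2 * i),
                          group = names(sets)[i]),
      bootstrap_disparity(s, n_reps, rarefy_to = n_min,
                          seed = seed_offset(seed, 2 * i + 1),
                          group = names(sets)[i])
    )
  })
  out <- do.call(rbind, out)
  class(out) <- c("disparity_profile", "data.frame")
  out
}

#' Disparity through time
#'
#' Bins taxa by their stratigraphic ranges and computes unrarefied and
#' rarefied (to the smallest non-empty bin) bootstrap disparity per bin.
#'
#' @param ord A [pco()] object or score matrix.
#' @param ranges Range table.
#' @param bins A [time_bins()] table (default [cynodont_bins()]).
#' @param n_reps Bootstrap replicates.
#' @param seed Optional RNG seed.
#' @param min_taxa Bins with fewer taxa are dropped (default 1).
#' @return A `disparity_profile` data frame, `group` holding bin labels.
#' @export
disparity_through_time <- function(ord, ranges, bins = cynodont_bins(),
                                   n_reps = 1000, seed = NULL, min_taxa = 1) {
  scores <- if (inherits(ord, "pco")) ord$scores else as.matrix(ord)
  member <- bin_taxa(ranges, bins)
  member <- lapply(member, intersect, rownames(scores))
  member <- member[lengths(member) >= min_taxa]
  if (length(member) == 0) stop("no bin contains any taxon", call. = FALSE)
  n_min <- min(lengths(member))
  out <- lapply(seq_along(member), function(i) {
    s <- scores[member[[i]], , drop = FALSE]
    rbind(
      bootstrap_disparity(s, n_reps, seed = seed_offset(seed, 2 * i),
                          group = names(member)[i]),
      bootstrap_disparity(s, n_reps, rarefy_to = min(n_min, nrow(s)),
                          seed = seed_offset(seed, 2 * i + 1),
                          group = names(member)[i])
    )
  })
  out <- do.call(rbind, out)
  class(out) <- c("disparity_profile", "data.frame")
  out
}

# Normalise group specifications to a named list of taxon vectors.
groups_as_list <- function(groups) {
  if (is.list(groups)) return(groups)
  if (is.null(names(groups))) stop("`groups` must be named by taxon", call. = FALSE)
  split(names(groups), as.character(groups))
}

# Derive distinct sub-seeds from one seed (kept below 2^31).
seed_offset <- function(seed, k) {
  if (is.null(seed)) NULL else (as.integer(seed) + 1009L * as.integer(k)) %% 2147483647L
}
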