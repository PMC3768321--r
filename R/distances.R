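# Inter-taxon distances ---------------------------------------------------

#' Generalized Euclidean distances from a character matrix
#'
#' Computes pairwise inter-taxon distances from discrete characters with
#' the mean-squared-difference imputation for characters that cannot be
#' compared in a pair (Wills-style GED). For a pair (j, k) the
#' per-character difference is `|x_j - x_k|` for ordered characters and
#' `1{x_j != x_k}` for unordered ones; polymorphic cells score the minimum
#' (or mean) difference over their member states. Squared differences of
#' characters not jointly scored are imputed as the weighted mean squared
#' difference over the pair's jointly scored characters, and
#' `GED = sqrt(sum_i w_i * delta_i^2)` over all characters.
#'
#' @param m A [character_matrix()].
#' @param polymorphism How a polymorphic cell is compared: `"min"`
#'   (default) or `"mean"` difference over member-state pairs.
#' @return A symmetric numeric matrix with zero diagonal and taxon labels
#'   as dimnames; attribute `comparable_counts` holds the per-pair number
#'   of jointly scored characters.
#' @export
ged_matrix <- function(m, polymorphism = c("min", "mean")) {
  polymorphism <- match.arg(polymorphism)
  n <- length(m$taxon_labels)
  if (n < 2) stop("need at least two taxa", call. = FALSE)
  C <- m$n_characters
  w <- m$weights
  sum_wd2 <- matrix(0, n, n)     # sum of weighted squared differences
  sum_wcomp <- matrix(0, n, n)   # sum of weights over comparable characters
  n_comp <- matrix(0L, n, n)     # unweighted comparable counts
  for (j in seq_len(C)) {
    sets <- cell_states(m$cells[, j])
    scored <- which(!vapply(sets, is.null, TRUE))
    if (length(scored) < 2) next
    single <- vapply(sets[scored], length, 1L) == 1L
    x <- rep(NA_real_, n)
    x[scored[single]] <- vapply(sets[scored[single]], `[[`, 0L, 1L)
    dmat <- matrix(NA_real_, n, n)
    ss <- scored[single]
    if (length(ss) >= 2) {
      if (m$ordering[j] == "ordered") {
        dmat[ss, ss] <- abs(outer(x[ss], x[ss], "-"))
      } else {
        dmat[ss, ss] <- (outer(x[ss], x[ss], "!=")) * 1
      }
    }
    poly <- scored[!single]
    for (a in poly) {
      for (b in scored) {
        if (a == b) next
        diffs <- if (m$ordering[j] == "ordered") {
          abs(outer(sets[[a]], sets[[b]], "-"))
        } else {
          (outer(sets[[a]], sets[[b]], "!=")) * 1
        }
        v <- if (polymorphism == "min") min(diffs) else mean(diffs)
        dmat[a, b] <- dmat[b, a] <- v
      }
    }
    comp <- !is.na(dmat)
    dmat[!comp] <- 0
    sum_wd2 <- sum_wd2 + w[j] * dmat^2
    sum_wcomp <- sum_wcomp + w[j] * comp
    n_comp <- n_comp + comp
  }
  diag(n_comp) <- C
  off <- upper.tri(n_comp)
  if (any(n_comp[off] == 0)) {
    idx <- which(n_comp == 0 & off, arr.ind = TRUE)
    pairs <- apply(idx, 1, function(r)
      paste(m$taxon_labels[r[1]], m$taxon_labels[r[2]], sep = " / "))
    stop(sprintf("taxon pairs share no jointly scored characters: %s",
                 paste(pairs, collapse = "; ")), call. = FALSE)
  }
  W <- sum(w)
  mean_wd2 <- sum_wd2 / sum_wcomp            # weighted mean squared difference
  diag(mean_wd2) <- 0
  d <- sqrt(sum_wd2 + (W - sum_wcomp) * mean_wd2)
  diag(d) <- 0
  dimnames(d) <- list(m$taxon_labels, m$taxon_labels)
  dimnames(n_comp) <- dimnames(d)
  attr(d, "comparable_counts") <- n_comp
  d
}

#' Patristic distances from a dated tree
#'
#' Sum of branch durations along the path between each pair of tips,
#' optionally square-root transformed (the transform used when comparing
#' phylogenetic with morphological distances).
#'
#' @param tree A rooted `phylo` with branch lengths in Myr.
#' @param transform `"none"` or `"sqrt"`.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree, transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch durations", call. = FALSE)
  d <- ape::cophenetic.phylo(tree)
  d <- d[tree$tip.label, tree$tip.label]
  if (transform == "sqrt") d <- sqrt(d)
  d
}

#' Drop taxa from a distance matrix
#'
#' Row/column deletion, used e.g. for Mantel tests that exclude one major
#' group at a time.
#'
#' @param d Symmetric labelled distance matrix.
#' @param drop Character vector of labels to remove.
#' @return The reduced matrix.
#' @export
subset_distances <- function(d, drop) {
  stop_if_not_square(d)
  missing <- setdiff(drop, rownames(d))
  if (length(missing) > 0)
    stop(sprintf("labels not in matrix: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  keep <- setdiff(rownames(d), drop)
  d[keep, keep, drop = FALSE]
}

#' Write a distance matrix
#'
#' @param d Symmetric labelled matrix.
#' @param path Output path.
#' @param format `"csv"` (square) or `"phylip"` (lower-triangle text).
#' @return `path`, invisibly.
#' @export
write_distances <- function(d, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(d, path)
  } else {
    n <- nrow(d)
    lines <- c(as.character(n), vapply(seq_len(n), function(i) {
      paste(c(rownames(d)[i], formatC(d[i, seq_len(i - 1)], format = "g",
                                      digits = 10)), collapse = "\t")
    }, ""))
    writeLines(lines, path)
  }
  invisible(path)
}
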