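# Principal coordinates analysis -----------------------------------------

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centring of `-0.5 * d^2` followed by eigendecomposition;
#' scores are eigenvectors scaled by the square root of their (positive)
#' eigenvalues. No correction is applied for negative eigenvalues; their
#' magnitude is reported in the result.
#'
#' @param d Symmetric labelled distance matrix with zero diagonal.
#' @param n_axes Number of axes to retain (default 20). If fewer axes have
#'   positive eigenvalues the result is truncated with a warning.
#' @return An object of class `pco`: list with `labels`, `scores`
#'   (taxa x retained axes), `eigenvalues` (full spectrum, descending) and
#'   `n_retained`.
#' @export
pco <- function(d, n_axes = 20) {
  stop_if_not_square(d)
  n <- nrow(d)
  if (n_axes > n - 1) stop("n_axes must be <= taxa - 1", call. = FALSE)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values) * 1e-12 & e$values > 0)
  k <- min(n_axes, length(pos))
  if (k < n_axes)
    warning(sprintf("only %d positive eigenvalues; returning %d axes", length(pos), k))
  scores <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k, k)
  rownames(scores) <- rownames(d)
  colnames(scores) <- paste0("PCo", seq_len(k))
  structure(list(labels = rownames(d), scores = scores,
                 eigenvalues = e$values, n_retained = k),
            class = "pco")
}

#' @export
print.pco <- function(x, ...) {
  pos <- sum(x$eigenvalues > 0)
  neg <- sum(x$eigenvalues < 0)
  cat(sprintf("pco: %d taxa, %d retained of %d positive axes (%d negative eigenvalues, min %.3g)\n",
              length(x$labels), x$n_retained, pos, neg,
              if (neg > 0) min(x$eigenvalues) else 0))
  invisible(x)
}
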