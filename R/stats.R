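# Permutation statistics and time-series tools ---------------------------

#' Mantel test between two distance matrices
#'
#' Correlation of the vectorized upper triangles, with a permutation null
#' built by simultaneously permuting the rows and columns of the second
#' matrix. The p-value is two-sided by default and uses the +1 rule (the
#' observed statistic counts as one permutation), so `p >= 1/(nperm + 1)`.
#'
#' @param d1,d2 Symmetric labelled distance matrices over the same taxa in
#'   the same order.
#' @param method Correlation coefficient: `"spearman"` (default),
#'   `"kendall"` or `"pearson"`.
#' @param nperm Number of random permutations (default 999).
#' @param exact If TRUE, enumerate all `n!` label permutations instead of
#'   sampling (`n <= 8`); `nperm` is ignored.
#' @param seed Optional RNG seed (local to the call).
#' @param two_sided Two-sided p (default) or one-sided (greater).
#' @return List of class `perm_test`: `statistic`, `coefficient`, `p`,
#'   `n_permutations`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "kendall", "pearson"),
                        nperm = 999, exact = FALSE, seed = NULL,
                        two_sided = TRUE) {
  method <- match.arg(method)
  stop_if_not_square(d1, "d1"); stop_if_not_square(d2, "d2")
  if (!identical(rownames(d1), rownames(d2)))
    stop("d1 and d2 must have identical labels in identical order", call. = FALSE)
  n <- nrow(d1)
  if (n < 3) stop("Mantel test needs >= 3 taxa", call. = FALSE)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  obs <- stats::cor(v1, d2[ut], method = method)
  stat_for <- function(perm) stats::cor(v1, d2[perm, perm][ut], method = method)
  if (exact) {
    perms <- all_permutations(n)
    null <- apply(perms[-1, , drop = FALSE], 1, stat_for)  # row 1 is identity
    p <- if (two_sided) (1 + sum(abs(null) >= abs(obs) - 1e-12)) / nrow(perms)
         else (1 + sum(null >= obs - 1e-12)) / nrow(perms)
    nperm <- nrow(perms) - 1
  } else {
    null <- with_seed(seed, vapply(seq_len(nperm), function(i)
      stat_for(sample.int(n)), numeric(1)))
    p <- perm_pvalue(obs, null, two_sided)
  }
  structure(list(statistic = obs, coefficient = method, p = p,
                 n_permutations = nperm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations)\n",
              x$coefficient, x$statistic, x$p, x$n_permutations))
  invisible(x)
}

# Pseudo-F from squared Euclidean distances and a grouping.
pseudo_f <- function(d2mat, groups) {
  n <- nrow(d2mat)
  g <- unique(groups)
  ss_total <- sum(d2mat[upper.tri(d2mat)]) / n
  ss_within <- sum(vapply(g, function(k) {
    idx <- which(groups == k)
    sum(d2mat[idx, idx][upper.tri(d2mat[idx, idx, drop = FALSE])]) / length(idx)
  }, numeric(1)))
  ss_among <- ss_total - ss_within
  (ss_among / (length(g) - 1)) / (ss_within / (n - length(g)))
}

#' Non-parametric MANOVA (permutational MANOVA) on ordination scores
#'
#' Pseudo-F computed from pairwise squared Euclidean distances among the
#' retained ordination axes, with a permutation test of group labels, plus
#' pairwise post hoc comparisons with Bonferroni-adjusted p-values.
#'
#' @param scores Taxa x axes matrix (or [pco()] object).
#' @param groups Group labels named by taxon, or in score row order.
#' @param nperm Number of permutations (default 9999).
#' @param seed Optional RNG seed.
#' @return List of class `npmanova`: `statistic` (F), `p`,
#'   `n_permutations`, `pairwise` (data frame with F, p, p_adj per pair).
#' @export
npmanova <- function(scores, groups, nperm = 9999, seed = NULL) {
  scores <- if (inherits(scores, "pco")) scores$scores else as.matrix(scores)
  groups <- align_groups(groups, rownames(scores), nrow(scores))
  d2 <- as.matrix(stats::dist(scores))^2
  run <- function(d2sub, gsub, np, sd) {
    obs <- pseudo_f(d2sub, gsub)
    null <- with_seed(sd, vapply(seq_len(np), function(i)
      pseudo_f(d2sub, gsub[sample.int(length(gsub))]), numeric(1)))
    list(statistic = obs, p = perm_pvalue(obs, null, two_sided = FALSE))
  }
  main <- run(d2, groups, nperm, seed)
  levs <- unique(groups)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    sel <- groups %in% pairs[[i]]
    r <- run(d2[sel, sel, drop = FALSE], groups[sel], nperm,
             seed_offset(seed, i))
    data.frame(group1 = pairs[[i]][1], group2 = pairs[[i]][2],
               F = r$statistic, p = r$p, stringsAsFactors = FALSE)
  }))
  pw$p_adj <- pmin(1, pw$p * nrow(pw))
  structure(list(statistic = main$statistic, coefficient = "F",
                 p = main$p, n_permutations = nperm, seed = seed,
                 pairwise = pw),
            class = c("npmanova", "perm_test"))
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n(n-1)/2` and mid-ranks for tied dissimilarities; group labels are
#' permuted for the p-value.
#'
#' @param d Symmetric labelled dissimilarity matrix.
#' @param groups Group labels named by taxon, or in matrix row order.
#' @param nperm Number of permutations (default 9999).
#' @param seed Optional RNG seed.
#' @return A `perm_test` list with `statistic` = R.
#' @export
anosim_test <- function(d, groups, nperm = 9999, seed = NULL) {
  stop_if_not_square(d)
  groups <- align_groups(groups, rownames(d), nrow(d))
  n <- nrow(d)
  ut <- upper.tri(d)
  rk <- rank(d[ut])
  M <- n * (n - 1) / 2
  same <- outer(groups, groups, "==")[ut]
  r_stat <- function(same_vec)
    (mean(rk[!same_vec]) - mean(rk[same_vec])) / (M / 2)
  obs <- r_stat(same)
  null <- with_seed(seed, vapply(seq_len(nperm), function(i) {
    gp <- groups[sample.int(n)]
    r_stat(outer(gp, gp, "==")[ut])
  }, numeric(1)))
  structure(list(statistic = obs, coefficient = "R",
                 p = perm_pvalue(obs, null, two_sided = FALSE),
                 n_permutations = nperm, seed = seed),
            class = "perm_test")
}

align_groups <- function(groups, labels, n) {
  g <- as.character(groups)
  if (!is.null(names(groups)) && !is.null(labels)) {
    miss <- setdiff(labels, names(groups))
    if (length(miss) > 0)
      stop(sprintf("no group for: %s", paste(miss, collapse = ", ")), call. = FALSE)
    g <- as.character(groups[labels])
  }
  if (length(g) != n) stop("groups do not match the data", call. = FALSE)
  if (length(unique(g)) < 2) stop("need >= 2 groups", call. = FALSE)
  g
}

#' Kruskal-Wallis test over groups of rates
#'
#' Tie-corrected H with a chi-square p-value (df = groups - 1); wraps
#' [stats::kruskal.test].
#'
#' @param samples List of >= 2 numeric vectors.
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(samples) {
  if (length(samples) < 2) stop("need >= 2 groups", call. = FALSE)
  kt <- stats::kruskal.test(samples)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Mann-Whitney U test
#'
#' Two-sided U with normal approximation and tie correction; wraps
#' [stats::wilcox.test].
#'
#' @param a,b Numeric vectors.
#' @return List: `U`, `p`.
#' @export
mann_whitney <- function(a, b) {
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Group-wise rate comparison battery
#'
#' Kruskal-Wallis across all groups plus post hoc pairwise Mann-Whitney
#' tests (raw and Bonferroni-adjusted p), on log10 rates by default.
#'
#' @param rate_groups Named list of positive rate vectors, one per group.
#' @param log10_transform Log10-transform rates first (default TRUE).
#' @return List: `kruskal` (H, df, p) and `pairwise` data frame.
#' @export
rate_group_tests <- function(rate_groups, log10_transform = TRUE) {
  x <- lapply(rate_groups, function(v) {
    v <- v[is.finite(v) & v > 0]
    if (log10_transform) log10(v) else v
  })
  kw <- kruskal_wallis(x)
  pairs <- utils::combn(names(x), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    mw <- mann_whitney(x[[pr[1]]], x[[pr[2]]])
    data.frame(group1 = pr[1], group2 = pr[2], U = mw$U, p = mw$p,
               stringsAsFactors = FALSE)
  }))
  pw$p_adj <- pmin(1, pw$p * nrow(pw))
  list(kruskal = kw, pairwise = pw)
}

#' Generalized differencing of a time series
#'
#' Removes both the linear trend on time and first-order autocorrelation
#' before correlation analysis: a linear trend is fitted, the lag-1
#' autocorrelation `rho` of its residuals estimated, and the series and
#' trend are quasi-differenced (`x_t - rho * x_{t-1}`), the first element
#' scaled by `sqrt(1 - rho^2)` (Prais-Winsten form).
#'
#' @param series Numeric vector (length >= 4).
#' @param times Numeric time coordinates (e.g. bin midpoints in Ma).
#' @return Numeric vector of the detrended series (same length), with the
#'   estimated `rho` as attribute `rho`.
#' @export
generalized_differencing <- function(series, times) {
  n <- length(series)
  if (n < 4) stop("series too short for generalized differencing (need >= 4)",
                  call. = FALSE)
  if (length(times) != n) stop("series and times lengths differ", call. = FALSE)
  fit <- stats::lm(series ~ times)
  res <- stats::residuals(fit)
  rho <- sum(res[-1] * res[-n]) / sum(res^2)
  trend <- stats::fitted(fit)
  gd <- function(x) c(x[1] * sqrt(1 - rho^2), x[-1] - rho * x[-n])
  out <- gd(series) - gd(trend)
  attr(out, "rho") <- rho
  out
}

#' Diversity-disparity correlation
#'
#' Pearson and Spearman correlations between a per-bin disparity series
#' and a diversity series, optionally after generalized differencing of
#' both.
#'
#' @param disparity,diversity Numeric series over the same time bins.
#' @param times Bin midpoints (Ma).
#' @param differenced Apply [generalized_differencing()] first.
#' @return Data frame with one row per coefficient: `method`, `estimate`,
#'   `p`.
#' @export
diversity_disparity_correlation <- function(disparity, diversity, times,
                                            differenced = FALSE) {
  if (length(disparity) != length(diversity))
    stop("series lengths differ", call. = FALSE)
  x <- disparity; y <- diversity
  if (differenced) {
    x <- as.numeric(generalized_differencing(x, times))
    y <- as.numeric(generalized_differencing(y, times))
  }
  rows <- lapply(c("pearson", "spearman"), function(mth) {
    ct <- suppressWarnings(stats::cor.test(x, y, method = mth, exact = FALSE))
    data.frame(method = mth, estimate = unname(ct$estimate), p = ct$p.value,
               differenced = differenced, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
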