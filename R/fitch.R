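# Parsimony optimization of discrete characters on a fixed tree ----------
#
# Unordered (Fitch) parsimony implemented as unit-cost Sankoff dynamic
# programming: a bottom-up pass computes, for every node and state, the
# minimum number of changes in the subtree given that state; a top-down
# pass then resolves one state per node. The resolution step is where
# ACCTRAN and DELTRAN differ: when staying in the parent's state and
# changing are equally parsimonious, ACCTRAN changes (pushing changes
# rootward) and DELTRAN stays (pushing them tipward). Remaining ties are
# broken by the lowest state index.

BIG_COST <- 1e9

#' Per-branch character changes under ACCTRAN or DELTRAN
#'
#' Counts character-state changes on every branch of a fixed rooted tree
#' under the chosen parsimony optimization. Characters are treated as
#' unordered multistate; missing cells as full ambiguity; polymorphic
#' cells as ambiguity over their member states. The per-character change
#' total equals the Fitch parsimony length for either optimization.
#'
#' @param tree Rooted `phylo` whose tips match the matrix taxa; branch
#'   lengths, if present, are carried through as durations.
#' @param m A [character_matrix()].
#' @param optimization `"acctran"` or `"deltran"`.
#' @return Object of class `branch_changes`: list with `edges` (data frame
#'   with `parent`, `child`, `raw_changes`, `duration`), `char_lengths`
#'   (per-character parsimony length), `node_states` (nodes x characters
#'   matrix of resolved states), `optimization`, and the `tree`.
#' @export
fitch_optimize <- function(tree, m, optimization = c("acctran", "deltran")) {
  optimization <- match.arg(optimization)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (!setequal(tree$tip.label, m$taxon_labels))
    stop("tree tips must match matrix taxa", call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  C <- m$n_characters
  alph <- pmax(vapply(seq_len(C), function(j)
    max(c(-1L, unlist(cell_states(m$cells[, j])))), integer(1)) + 1L, 1L)
  K <- max(alph)
  cells <- m$cells[match(tree$tip.label, m$taxon_labels), , drop = FALSE]

  # tip costs: 0 for observed/ambiguous states within the alphabet, BIG
  # otherwise
  cost <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) {
    cm <- matrix(BIG_COST, K, C)
    sets <- cell_states(cells[i, ])
    for (j in seq_len(C)) {
      s <- sets[[j]]
      if (is.null(s)) cm[seq_len(alph[j]), j] <- 0
      else cm[s + 1L, j] <- 0
    }
    cost[[i]] <- cm
  }

  edge <- tree$edge
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (v in (ntip + 1L):(ntip + nnode)) cost[[v]] <- matrix(0, K, C)
  for (e in post) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    cc <- cost[[ch]]
    cmin1 <- apply(cc, 2, min)
    contrib <- pmin(cc, rep(cmin1 + 1, each = K))
    cost[[p]] <- cost[[p]] + contrib
  }
  root <- ntip + 1L
  char_lengths <- apply(cost[[root]], 2, min)

  # top-down resolution
  state <- matrix(NA_integer_, ntip + nnode, C)
  state[root, ] <- max.col(-t(cost[[root]]), ties.method = "first")
  pre <- rev(post)
  raw <- numeric(nrow(edge))
  for (e in pre) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    cc <- cost[[ch]]
    sp <- state[p, ]
    stay <- cc[cbind(sp, seq_len(C))]
    i1 <- max.col(-t(cc), ties.method = "first")
    m1 <- cc[cbind(i1, seq_len(C))]
    cc2 <- cc
    cc2[cbind(i1, seq_len(C))] <- BIG_COST * 2
    i2 <- max.col(-t(cc2), ties.method = "first")
    m2 <- cc2[cbind(i2, seq_len(C))]
    alt_cost <- ifelse(i1 == sp, m2, m1)
    alt_state <- ifelse(i1 == sp, i2, i1)
    change <- if (optimization == "acctran") {
      alt_cost + 1 <= stay
    } else {
      alt_cost + 1 < stay
    }
    state[ch, ] <- ifelse(change, alt_state, sp)
    raw[e] <- sum(m$weights[change])
  }

  structure(list(
    edges = data.frame(parent = edge[, 1], child = edge[, 2],
                       raw_changes = raw,
                       duration = tree$edge.length %||% rep(NA_real_, nrow(edge))),
    char_lengths = char_lengths,
    node_states = state - 1L,
    optimization = optimization,
    tree = tree
  ), class = "branch_changes")
}

#' @export
print.branch_changes <- function(x, ...) {
  cat(sprintf("branch_changes (%s): %d branches, %.0f total changes, tree length %d\n",
              x$optimization, nrow(x$edges), sum(x$edges$raw_changes),
              sum(x$char_lengths)))
  invisible(x)
}

#' Correct branch change counts for missing data
#'
#' Scales the raw per-branch change counts by the fraction of characters
#' actually scorable on the branch (the patristic-dissimilarity
#' correction). A character is scorable at a tip when the tip is scored
#' for it, and at an internal node when at least one descendant tip is; a
#' branch's scorable fraction is the fraction of characters scorable at
#' both of its endpoints, and `corrected = raw / fraction`.
#'
#' @param changes A `branch_changes` object from [fitch_optimize()].
#' @param m The [character_matrix()] used to compute it.
#' @return `changes` with columns `scorable_fraction`, `corrected_changes`
#'   and logical `excluded` (TRUE where the fraction is 0) added to
#'   `$edges`.
#' @export
completeness_correct <- function(changes, m) {
  tree <- changes$tree
  ntip <- length(tree$tip.label)
  C <- m$n_characters
  scored <- !is.na(m$cells[match(tree$tip.label, m$taxon_labels), , drop = FALSE])
  scorable <- matrix(FALSE, ntip + tree$Nnode, C)
  scorable[seq_len(ntip), ] <- scored
  post <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  for (e in post) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    scorable[p, ] <- scorable[p, ] | scorable[ch, ]
  }
  # parent's scorable set contains the child's, so the branch fraction is
  # the child's
  frac <- rowSums(scorable)[changes$edges$child] / C
  excluded <- frac == 0
  if (any(excluded))
    warning(sprintf("%d branch(es) with no scorable characters excluded",
                    sum(excluded)))
  changes$edges$scorable_fraction <- frac
  changes$edges$corrected_changes <- ifelse(excluded, NA_real_,
                                            changes$edges$raw_changes / frac)
  changes$edges$excluded <- excluded
  changes
}

#' Per-branch evolutionary rates
#'
#' Rates in changes per Myr: corrected change counts divided by branch
#' durations. Zero-duration branches and zero-rate branches are flagged
#' for exclusion from downstream analyses; non-zero rates are also
#' returned log10-transformed.
#'
#' @param changes A `branch_changes` object with corrected counts (see
#'   [completeness_correct()]); if uncorrected, raw counts are used with a
#'   warning.
#' @return `changes` with `rate`, `log10_rate` and updated `excluded`
#'   columns in `$edges`.
#' @export
branch_rates <- function(changes) {
  ed <- changes$edges
  if (is.null(ed$corrected_changes)) {
    warning("no completeness correction applied; using raw change counts")
    ed$corrected_changes <- ed$raw_changes
    ed$excluded <- FALSE
  }
  if (anyNA(ed$duration)) stop("tree has no branch durations", call. = FALSE)
  zero_dur <- ed$duration <= 0
  if (any(zero_dur))
    warning(sprintf("%d zero-duration branch(es) excluded", sum(zero_dur)))
  ed$rate <- ifelse(zero_dur | ed$excluded, NA_real_,
                    ed$corrected_changes / ed$duration)
  ed$excluded <- ed$excluded | zero_dur | (!is.na(ed$rate) & ed$rate == 0)
  ed$log10_rate <- ifelse(ed$excluded | is.na(ed$rate), NA_real_, log10(ed$rate))
  changes$edges <- ed
  changes
}

#' Likelihood-ratio tests of branch-rate equality
#'
#' Models the corrected change count of branch i as Poisson with mean
#' `rate * duration` (a Gamma-function likelihood, since corrected counts
#' are real-valued). The global test compares the single-rate null with
#' the per-branch saturated model (df = branches - 1); each per-branch
#' test compares that branch's own rate against the pooled rest (df = 1).
#' Branches with Benjamini-Hochberg adjusted p below `alpha` are flagged
#' `high` or `low` by the sign of their rate relative to the pooled rest.
#'
#' Zero-change branches are retained here (dropping them would truncate
#' the count distribution and break the test's calibration under the
#' null); only zero-duration branches and branches with no scorable
#' characters are excluded. The zero-rate exclusion applies to log-rate
#' analyses, not to these tests.
#'
#' @param changes A `branch_changes` object after [branch_rates()].
#' @param alpha Flagging level (default 0.05).
#' @return List of class `rate_tests`: `global` (statistic, df, p) and
#'   `table` (per-branch statistic, p, p_adj, flag).
#' @export
rate_equality_tests <- function(changes, alpha = 0.05) {
  ed <- changes$edges
  if (is.null(ed$rate)) changes <- suppressWarnings(branch_rates(changes))
  ed <- changes$edges
  keep <- !is.na(ed$duration) & ed$duration > 0 & !is.na(ed$corrected_changes)
  cc <- ed$corrected_changes[keep]
  dd <- ed$duration[keep]
  if (sum(keep) < 2) stop("need >= 2 usable branches", call. = FALSE)
  xlog <- function(c, v) ifelse(c == 0, 0, c * log(v))  # 0 * log(0) := 0
  loglik <- function(lambda, c, d) sum(xlog(c, lambda * d) - lambda * d)
  # lgamma(c+1) terms cancel in every ratio and are omitted
  l_sat <- sum(xlog(cc, cc) - cc)                    # lambda_i = c_i / d_i
  l_null <- loglik(sum(cc) / sum(dd), cc, dd)
  g_stat <- 2 * (l_sat - l_null)
  g_df <- sum(keep) - 1
  global <- list(statistic = g_stat, df = g_df,
                 p = stats::pchisq(g_stat, g_df, lower.tail = FALSE))
  idx <- which(keep)
  stat_i <- p_i <- rep(NA_real_, nrow(ed))
  dir_i <- rep(NA_character_, nrow(ed))
  for (k in seq_along(idx)) {
    ci <- cc[k]; di <- dd[k]
    cr <- sum(cc[-k]); dr <- sum(dd[-k])
    # the rest-of-tree term must stay branch-wise so the c*log(d)
    # constants cancel against the null term
    l1 <- loglik(ci / di, ci, di) + loglik(cr / dr, cc[-k], dd[-k])
    l0 <- loglik(sum(cc) / sum(dd), cc, dd)
    stat_i[idx[k]] <- 2 * (l1 - l0)
    p_i[idx[k]] <- stats::pchisq(2 * (l1 - l0), 1, lower.tail = FALSE)
    dir_i[idx[k]] <- if (ci / di > cr / dr) "high" else "low"
  }
  p_adj <- rep(NA_real_, nrow(ed))
  p_adj[idx] <- stats::p.adjust(p_i[idx], method = "BH")
  flag <- ifelse(!is.na(p_adj) & p_adj < alpha, dir_i, "none")
  flag[is.na(p_adj)] <- NA_character_
  structure(list(global = global,
                 table = data.frame(parent = ed$parent, child = ed$child,
                                    statistic = stat_i, p = p_i,
                                    p_adj = p_adj, flag = flag)),
            class = "rate_tests")
}

#' @export
print.rate_tests <- function(x, ...) {
  cat(sprintf("rate equality LRT: statistic = %.2f, df = %d, p = %.3g; %d high, %d low\n",
              x$global$statistic, x$global$df, x$global$p,
              sum(x$table$flag == "high", na.rm = TRUE),
              sum(x$table$flag == "low", na.rm = TRUE)))
  invisible(x)
}

#' Assign branch rates to time intervals
#'
#' Every non-excluded branch contributes its (single) rate to each time
#' bin its duration overlaps.
#'
#' @param changes A `branch_changes` object after [branch_rates()], whose
#'   tree carries node ages (see [node_ages()]).
#' @param bins A [time_bins()] table (default [cynodont_rate_bins()]).
#' @return Named list mapping bin label to the numeric rates realized in
#'   that bin; empty bins are dropped.
#' @export
rates_by_interval <- function(changes, bins = cynodont_rate_bins()) {
  ed <- changes$edges
  if (is.null(ed$rate)) stop("run branch_rates() first", call. = FALSE)
  ages <- node_ages(changes$tree)
  p_age <- ages[ed$parent]
  c_age <- ages[ed$child]
  out <- lapply(seq_len(nrow(bins)), function(b) {
    hit <- !ed$excluded & p_age > bins$end[b] & c_age < bins$start[b]
    ed$rate[hit]
  })
  names(out) <- bins$label
  out[lengths(out) > 0]
}

#' Regression of rates on interval midpoints
#'
#' Ordinary least squares of log10 rate on bin midpoint (Ma before
#' present), with Kendall's rank correlation (normal approximation,
#' tie-corrected) measuring strength and significance of the trend.
#'
#' @param interval_rates Named list from [rates_by_interval()].
#' @param bins The [time_bins()] table the intervals refer to.
#' @return List: `slope`, `intercept`, `tau`, `p`, `n`.
#' @export
rate_time_regression <- function(interval_rates, bins) {
  mid <- stats::setNames(bins$midpoint, bins$label)
  labs <- names(interval_rates)
  if (!all(labs %in% names(mid)))
    stop("interval labels not found in bins", call. = FALSE)
  x <- rep(mid[labs], lengths(interval_rates))
  y <- log10(unlist(interval_rates))
  ok <- is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) stop("need rates in >= 2 intervals", call. = FALSE)
  fit <- stats::lm(y ~ x)
  kt <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         exact = FALSE))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       tau = unname(kt$estimate), p = kt$p.value, n = length(y))
}

#' Write a tree with branch lengths replaced by rates
#'
#' @param changes A `branch_changes` object after [branch_rates()].
#' @param path Newick output path; excluded branches get length 0.
#' @return `path`, invisibly.
#' @export
write_rates_tree <- function(changes, path) {
  tr <- changes$tree
  r <- changes$edges$rate
  r[is.na(r)] <- 0
  tr$edge.length <- r
  ape::write.tree(tr, path)
  invisible(path)
}
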