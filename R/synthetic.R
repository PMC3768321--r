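# Synthetic data: dated trees, Mk characters, missingness, ranges --------

#' Simulate a dated tree
#'
#' Birth-death tree conditioned on the number of tips (via [ape::rphylo]),
#' with node ages in Ma attached; the youngest tips sit at `present_age`.
#'
#' @param n_taxa Number of tips.
#' @param birth,death Speciation and extinction rates (per lineage per
#'   Myr); defaults 0.08 and 0.03 give root ages around 60 Myr at
#'   study-like tip counts.
#' @param seed Optional RNG seed (local to the call).
#' @param present_age Age (Ma) of the youngest tips (default 0).
#' @return A rooted `phylo` with branch durations in Myr and a
#'   `node_ages` attribute (see [node_ages()]).
#' @export
simulate_dated_tree <- function(n_taxa, birth = 0.08, death = 0.03,
                                seed = NULL, present_age = 0) {
  if (n_taxa < 2) stop("n_taxa must be >= 2", call. = FALSE)
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = birth, death = death))
  tr$tip.label <- sprintf("t%02d", seq_len(n_taxa))
  depth <- ape::node.depth.edgelength(tr)
  ages <- max(depth) - depth + present_age
  attr(tr, "node_ages") <- ages
  attr(tr, "root_age") <- ages[n_taxa + 1L]
  tr
}

# Transition sampling for the equal-rates Mk model: after time t at leave
# rate a, P(child = parent) = 1/k + (k-1)/k * exp(-k a t / (k - 1)).
mk_p_same <- function(k, a, t) 1 / k + (k - 1) / k * exp(-k * a * t / (k - 1))

#' Simulate discrete characters on a dated tree
#'
#' Equal-rates Mk evolution: each character draws its state count, starts
#' from a uniform root state, and changes along each branch at the given
#' rate (per Myr) times any clade multiplier, with the new state uniform
#' over the remaining states. Invariant characters can be resampled so
#' the matrix contains only variable characters, as cladistic matrices
#' do.
#'
#' @param tree Dated `phylo`.
#' @param n_characters Number of characters (default 150).
#' @param rate Expected state changes per Myr per character (default
#'   0.005, giving a few changes per character over a study-scale tree).
#' @param state_counts Possible states per character; either a single
#'   integer, or a vector sampled with `state_probs`.
#' @param state_probs Sampling weights for `state_counts` (default favours
#'   binary and three-state characters).
#' @param clade_multipliers Named numeric vector: names are internal node
#'   numbers (ape numbering) or tip labels whose MRCA defines the clade;
#'   all branches within (and including the stem of) each clade get their
#'   rate multiplied.
#' @param ensure_variable Resample characters with fewer than two observed
#'   states (default TRUE).
#' @param seed Optional RNG seed.
#' @return A [character_matrix()].
#' @export
simulate_characters <- function(tree, n_characters = 150, rate = 0.005,
                                state_counts = 2:5,
                                state_probs = c(0.55, 0.25, 0.12, 0.08),
                                clade_multipliers = NULL,
                                ensure_variable = TRUE, seed = NULL) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  mult <- rep(1, nrow(edge))
  if (!is.null(clade_multipliers)) {
    for (nm in names(clade_multipliers)) {
      node <- suppressWarnings(as.integer(nm))
      if (is.na(node)) node <- match(nm, tree$tip.label)
      if (is.na(node)) stop(sprintf("unknown clade anchor '%s'", nm), call. = FALSE)
      inside <- clade_edges(tree, node)
      mult[inside] <- mult[inside] * clade_multipliers[[nm]]
    }
  }
  pre <- order_edges_preorder(tree)
  with_seed(seed, {
    draw_char <- function() {
      k <- if (length(state_counts) == 1) state_counts
           else sample(state_counts, 1, prob = state_probs)
      st <- integer(ntip + tree$Nnode)
      st[ntip + 1L] <- sample.int(k, 1) - 1L
      for (e in pre) {
        p <- st[edge[e, 1]]
        if (stats::runif(1) < mk_p_same(k, rate * mult[e], elen[e])) {
          st[edge[e, 2]] <- p
        } else {
          others <- setdiff(seq_len(k) - 1L, p)
          st[edge[e, 2]] <- if (length(others) == 1) others
                            else sample(others, 1)
        }
      }
      st[seq_len(ntip)]
    }
    cols <- vector("list", n_characters)
    for (j in seq_len(n_characters)) {
      col <- draw_char()
      if (ensure_variable) {
        tries <- 0
        while (length(unique(col)) < 2 && tries < 1000) {
          col <- draw_char(); tries <- tries + 1
        }
      }
      cols[[j]] <- col
    }
    cells <- do.call(cbind, lapply(cols, as.character))
    rownames(cells) <- tree$tip.label
    character_matrix(cells)
  })
}

# Edge indices inside the clade of `node`, including its stem branch.
clade_edges <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(which(tree$edge[, 2] == node))
  inside <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% inside, 2]
    new <- setdiff(kids, inside)
    if (length(new) == 0) break
    inside <- c(inside, new)
  }
  which(tree$edge[, 2] %in% inside)
}

#' Mask cells as missing
#'
#' Independently masks each cell of each taxon at that taxon's missingness
#' fraction, emulating incomplete fossil coding.
#'
#' @param m A [character_matrix()].
#' @param fraction Scalar in `[0, 1)` or per-taxon vector (named or in
#'   taxon order).
#' @param seed Optional RNG seed.
#' @return A [character_matrix()] with cells replaced by `NA`.
#' @export
apply_missingness <- function(m, fraction, seed = NULL) {
  ntax <- length(m$taxon_labels)
  f <- if (!is.null(names(fraction))) fraction[m$taxon_labels]
       else rep_len(fraction, ntax)
  if (any(is.na(f)) || any(f < 0) || any(f >= 1))
    stop("missingness fractions must be in [0, 1) for every taxon", call. = FALSE)
  cells <- with_seed(seed, {
    out <- m$cells
    for (i in seq_len(ntax)) {
      mask <- stats::runif(m$n_characters) < f[i]
      out[i, mask] <- NA
    }
    out
  })
  character_matrix(cells, ordering = m$ordering, weights = m$weights)
}

#' Simulate stratigraphic ranges from a dated tree
#'
#' Each tip's FAD is its age plus an exponential preservation lag toward
#' older ages, truncated at the origin of its subtending branch; the LAD
#' is the FAD minus an exponential observed duration, truncated at the tip
#' age minus a small buffer (and kept positive).
#'
#' @param tree Dated `phylo` with node ages (see [node_ages()]).
#' @param lag_rate Rate of the exponential preservation lag (per Myr;
#'   default 0.5, i.e. mean 2 Myr).
#' @param duration_rate Rate of the exponential observed duration
#'   (default 0.5).
#' @param buffer LADs may extend at most this far below the tip age
#'   (default 0.5 Myr).
#' @param seed Optional RNG seed.
#' @return Range `data.frame` (`taxon`, `fad`, `lad`).
#' @export
simulate_ranges <- function(tree, lag_rate = 0.5, duration_rate = 0.5,
                            buffer = 0.5, seed = NULL) {
  ages <- node_ages(tree)
  ntip <- length(tree$tip.label)
  parent_age <- ages[tree$edge[, 1]][match(seq_len(ntip), tree$edge[, 2])]
  with_seed(seed, {
    tip_age <- ages[seq_len(ntip)]
    lag <- stats::rexp(ntip, lag_rate)
    fad <- pmin(tip_age + lag, parent_age)
    fad <- pmax(fad, tip_age + 1e-6)
    dur <- stats::rexp(ntip, duration_rate)
    lad <- pmax(fad - dur, tip_age - buffer)
    lad <- pmax(pmin(lad, fad), 1e-6)
    data.frame(taxon = tree$tip.label, fad = fad, lad = lad,
               stringsAsFactors = FALSE)
  })
}

#' Split tips into three groups by tree structure
#'
#' Emulates a basal paraphyletic array plus two derived clades: the
#' poorer side of the root split becomes the `basal` group and the richer
#' side is split at its own basal node into `clade_1` and `clade_2`.
#'
#' @param tree Rooted `phylo` with >= 4 tips.
#' @return Named character vector mapping tip label to group, with the
#'   anchor nodes of the two clades as attribute `clade_nodes`.
#' @export
label_three_groups <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  sizes <- vapply(kids, function(k) length(tips_below(tree, k)), integer(1))
  rich <- kids[which.max(sizes)]
  basal <- setdiff(seq_len(ntip), tips_below(tree, rich))
  sub_kids <- tree$edge[tree$edge[, 1] == rich, 2]
  if (rich <= ntip || length(sub_kids) < 2)
    stop("tree too small to define three groups", call. = FALSE)
  g1 <- tips_below(tree, sub_kids[1])
  g2 <- setdiff(tips_below(tree, rich), g1)
  out <- rep(NA_character_, ntip)
  out[basal] <- "basal"
  out[g1] <- "clade_1"
  out[g2] <- "clade_2"
  names(out) <- tree$tip.label
  attr(out, "clade_nodes") <- c(clade_1 = sub_kids[1],
                                clade_2 = if (length(sub_kids) == 2) sub_kids[2]
                                          else NA_integer_)
  out
}

tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  inside <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% inside, 2]
    new <- setdiff(kids, inside)
    if (length(new) == 0) break
    inside <- c(inside, new)
  }
  inside[inside <= ntip]
}

#' Simulate a complete study dataset
#'
#' One call generating every input the pipeline needs: a dated tree,
#' an Mk character matrix with optional clade rate elevation and
#' missing-data masking, preservation-thinned stratigraphic ranges,
#' three group labels and a covering set of time bins.
#'
#' @param n_taxa,n_characters Dataset size (defaults 54 and 150, the
#'   study-scale configuration).
#' @param rate Character change rate per Myr (default 0.005).
#' @param missingness Per-taxon missingness range; fractions are drawn
#'   uniformly between the two values (default 0.05-0.5).
#' @param clade_rate_multiplier Rate multiplier applied to `clade_1`
#'   (default 1 = homogeneous).
#' @param n_bins Number of covering time bins (default 11).
#' @param seed RNG seed driving every stochastic step.
#' @return List: `tree`, `matrix`, `ranges`, `groups`, `bins`, `seed`.
#' @export
simulate_study <- function(n_taxa = 54, n_characters = 150, rate = 0.005,
                           missingness = c(0.05, 0.5),
                           clade_rate_multiplier = 1, n_bins = 11,
                           seed = NULL) {
  tree <- simulate_dated_tree(n_taxa, seed = seed_offset(seed, 1))
  groups <- label_three_groups(tree)
  mults <- NULL
  if (clade_rate_multiplier != 1) {
    node <- attr(groups, "clade_nodes")[["clade_1"]]
    mults <- stats::setNames(clade_rate_multiplier, as.character(node))
  }
  m <- simulate_characters(tree, n_characters = n_characters, rate = rate,
                           clade_multipliers = mults,
                           seed = seed_offset(seed, 2))
  frac <- with_seed(seed_offset(seed, 3),
                    stats::runif(n_taxa, missingness[1], missingness[2]))
  names(frac) <- tree$tip.label
  m <- apply_missingness(m, frac, seed = seed_offset(seed, 4))
  ranges <- simulate_ranges(tree, seed = seed_offset(seed, 5))
  oldest <- max(ranges$fad) + 1e-6
  youngest <- max(min(ranges$lad) - 1e-6, 0)
  edges <- seq(oldest, youngest, length.out = n_bins + 1)
  bins <- time_bins(sprintf("b%02d", seq_len(n_bins)),
                    start = edges[-(n_bins + 1)], end = edges[-1])
  list(tree = tree, matrix = m, ranges = ranges, groups = groups,
       bins = bins, seed = seed)
}
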