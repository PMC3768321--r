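# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Minimum number of unordered state changes on a rooted tree for one
# character, by exhaustive enumeration of all ancestral state assignments.
# `tip_sets` is a list (in ape tip order) of allowed integer state sets.
brute_force_length <- function(tree, tip_sets, n_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  combos <- expand.grid(rep(list(seq_len(n_states) - 1L), nnode))
  tip_combos <- expand.grid(tip_sets)
  best <- Inf
  for (i in seq_len(nrow(tip_combos))) {
    tipv <- as.integer(tip_combos[i, ])
    for (j in seq_len(nrow(combos))) {
      st <- c(tipv, as.integer(combos[j, ]))
      changes <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
      if (changes < best) best <- changes
    }
  }
  best
}

# Naive O(n^2) Ripley's K in 3-D with optional translation correction.
naive_k3d <- function(points, r_grid, box, correction = "translation") {
  n <- nrow(points)
  L <- box[2, ] - box[1, ]
  V <- prod(L)
  k <- numeric(length(r_grid))
  for (a in seq_along(r_grid)) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      dx <- abs(points[i, ] - points[j, ])
      if (sqrt(sum(dx^2)) <= r_grid[a]) {
        w <- if (correction == "translation") V / prod(L - dx) else 1
        s <- s + w
      }
    }
    k[a] <- V * s / (n * (n - 1))
  }
  k
}

# Kendall's tau by direct concordant/discordant pair counting (no ties
# assumed in the inputs used with it).
naive_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(n, 2)
}

# Random small character matrix (complete unless miss_frac > 0).
random_matrix <- function(n_taxa, n_chars, n_states = 2, miss_frac = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cells <- matrix(as.character(sample(0:(n_states - 1),
                                      n_taxa * n_chars, replace = TRUE)),
                  n_taxa, n_chars)
  if (miss_frac > 0)
    cells[matrix(runif(length(cells)) < miss_frac, n_taxa)] <- NA
  rownames(cells) <- paste0("T", seq_len(n_taxa))
  character_matrix(cells)
}

# Labelled symmetric random distance matrix.
random_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("T", seq_len(n)), paste0("T", seq_len(n)))
  d
}
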