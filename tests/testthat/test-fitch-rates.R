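# local copies of small tree utilities so tests stay independent of
# package internals
cell_states_for_test <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell)) NULL
    else as.integer(strsplit(cell, "/", fixed = TRUE)[[1]])
  })
}

tips_below_for_test <- function(tree, node) {
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

test_that("simple four-tip characters optimize as expected", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- character_matrix(rbind(A = "0", B = "0", C = "1", D = "1"))
  for (opt in c("acctran", "deltran")) {
    bc <- fitch_optimize(tr, m, opt)
    expect_equal(sum(bc$edges$raw_changes), 1)
    expect_equal(bc$char_lengths, 1)
    # the single change sits on an internal branch
    internal <- bc$edges$child > 4
    expect_equal(sum(bc$edges$raw_changes[internal]), 1)
  }
  # autapomorphy of A lands on A's terminal branch under both optimizations
  m2 <- character_matrix(rbind(A = "1", B = "0", C = "0", D = "0"))
  for (opt in c("acctran", "deltran")) {
    bc <- fitch_optimize(tr, m2, opt)
    a_edge <- which(bc$edges$child == which(tr$tip.label == "A"))
    expect_equal(bc$edges$raw_changes[a_edge], 1)
    expect_equal(sum(bc$edges$raw_changes), 1)
  }
})

test_that("ACCTRAN accelerates and DELTRAN delays an ambiguous change", {
  # pectinate tree with 1,0,1,0 from tip to outgroup: two reconstructions
  # tie; ACCTRAN takes the reversal (change nearer the root), DELTRAN the
  # parallelism (changes on the terminals)
  tr <- ape::read.tree(text = "(((A,B),C),D);")
  m <- character_matrix(rbind(A = "1", B = "0", C = "1", D = "0"))
  acc <- fitch_optimize(tr, m, "acctran")
  del <- fitch_optimize(tr, m, "deltran")
  expect_equal(sum(acc$edges$raw_changes), 2)
  expect_equal(sum(del$edges$raw_changes), 2)
  depth_of <- function(bc) {
    # mean number of edges between a changed branch and the root
    ed <- bc$edges[bc$edges$raw_changes > 0, ]
    mean(vapply(seq_len(nrow(ed)), function(i) {
      d <- 0; node <- ed$parent[i]
      while (node != 5) { node <- bc$edges$parent[bc$edges$child == node]; d <- d + 1 }
      d
    }, numeric(1)))
  }
  expect_lt(depth_of(acc), depth_of(del))
})

test_that("branch-change totals equal exhaustive-enumeration parsimony length", {
  for (s in 1:8) {
    set.seed(s)
    ntip <- sample(4:6, 1)
    tr <- ape::rtree(ntip)
    nst <- sample(2:4, 1)
    cells <- matrix(as.character(sample(0:(nst - 1), ntip * 3, replace = TRUE)),
                    ntip, 3)
    cells[1, 1] <- NA                         # one missing cell
    cells[2, 2] <- paste(sort(sample(0:(nst - 1), 2)), collapse = "/")
    rownames(cells) <- tr$tip.label
    m <- character_matrix(cells)
    oracle <- vapply(1:3, function(j) {
      sets <- lapply(cell_states_for_test(cells[, j]), function(st)
        if (is.null(st)) 0:(nst - 1) else st)
      brute_force_length(tr, sets, nst)
    }, numeric(1))
    for (opt in c("acctran", "deltran")) {
      bc <- fitch_optimize(tr, m, opt)
      expect_equal(unname(bc$char_lengths), unname(oracle))
      # per-branch changes sum to the per-character lengths
      expect_equal(sum(bc$edges$raw_changes), sum(oracle))
    }
  }
})

test_that("tree length agrees with phangorn's Fitch score on complete data", {
  skip_if_not_installed("phangorn")
  for (s in 1:3) {
    set.seed(100 + s)
    tr <- ape::rtree(8)
    m <- random_matrix(8, 25, n_states = 3)
    rownames(m$cells) <- tr$tip.label
    m <- character_matrix(m$cells)
    pd <- phangorn::phyDat(m$cells, type = "USER", levels = c("0", "1", "2"))
    expect_equal(sum(fitch_optimize(tr, m)$char_lengths),
                 phangorn::fitch(tr, pd))
  }
})

test_that("completeness correction rescales by scorable fraction", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # fully coded: corrected equals raw everywhere
  m <- random_matrix(4, 10, n_states = 2, seed = 9)
  rownames(m$cells) <- tr$tip.label
  m <- character_matrix(m$cells)
  bc <- completeness_correct(fitch_optimize(tr, m), m)
  expect_equal(bc$edges$scorable_fraction, rep(1, 6))
  expect_equal(bc$edges$corrected_changes, bc$edges$raw_changes)
  # tip scored for half its characters doubles its corrected count
  cells <- m$cells
  cells["A", 1:5] <- NA
  m2 <- character_matrix(cells)
  bc2 <- completeness_correct(fitch_optimize(tr, m2), m2)
  a_edge <- which(bc2$edges$child == which(tr$tip.label == "A"))
  expect_equal(bc2$edges$scorable_fraction[a_edge], 0.5)
  expect_equal(bc2$edges$corrected_changes[a_edge],
               2 * bc2$edges$raw_changes[a_edge])
  # internal branches count characters scorable in >= 1 descendant tip
  int_edge <- which(bc2$edges$child == 5 | bc2$edges$child == 6)
  expect_true(all(bc2$edges$scorable_fraction[int_edge] == 1))
})

test_that("branch rates divide corrected changes by durations", {
  tr <- ape::read.tree(text = "(A:3,B:3);")
  m <- character_matrix(rbind(A = as.character(rep(0, 8)),
                              B = as.character(c(rep(1, 6), 0, 0))))
  bc <- branch_rates(completeness_correct(fitch_optimize(tr, m), m))
  rates <- bc$edges$rate
  expect_equal(sum(bc$edges$raw_changes), 6)
  expect_equal(sum(rates, na.rm = TRUE), 2)          # 6 changes / 3 Myr
  expect_equal(bc$edges$log10_rate[which.max(rates)],
               log10(max(rates, na.rm = TRUE)))
  # zero-rate branches are flagged excluded
  expect_true(any(bc$edges$excluded[bc$edges$raw_changes == 0] |
                  is.na(bc$edges$rate[bc$edges$raw_changes == 0])))
})

test_that("rates are equivariant under uniform duration rescaling", {
  sim <- simulate_study(n_taxa = 12, n_characters = 30, seed = 77)
  bc <- suppressWarnings(
    branch_rates(completeness_correct(fitch_optimize(sim$tree, sim$matrix),
                                      sim$matrix)))
  tr2 <- sim$tree
  tr2$edge.length <- tr2$edge.length * 4
  bc2 <- suppressWarnings(
    branch_rates(completeness_correct(fitch_optimize(tr2, sim$matrix),
                                      sim$matrix)))
  expect_equal(bc2$edges$rate, bc$edges$rate / 4, tolerance = 1e-9)
})

test_that("equal branch rates give a near-zero global LRT and no flags", {
  tr <- ape::read.tree(text = "((A:2,B:2):2,(C:2,D:2):2);")
  bc <- list(tree = tr,
             edges = data.frame(parent = c(5, 6, 6, 5, 7, 7),
                                child = c(6, 1, 2, 7, 3, 4),
                                raw_changes = rep(4, 6),
                                duration = rep(2, 6),
                                corrected_changes = rep(4, 6),
                                excluded = rep(FALSE, 6),
                                rate = rep(2, 6)))
  class(bc) <- "branch_changes"
  rt <- rate_equality_tests(bc)
  expect_lt(abs(rt$global$statistic), 1e-9)
  expect_true(all(rt$table$flag == "none", na.rm = TRUE))
})

test_that("per-branch LRT matches direct numerical maximization", {
  set.seed(5)
  n <- 6
  cc <- runif(n, 0.5, 12)
  dd <- runif(n, 0.5, 5)
  ll <- function(lam, c, d) sum(c * log(lam * d) - lam * d)
  for (i in 1:2) {
    num <- function(f) stats::optimize(f, c(1e-6, 100), maximum = TRUE)$objective
    l1 <- num(function(l) ll(l, cc[i], dd[i])) +
      num(function(l) ll(l, cc[-i], dd[-i]))
    l0 <- num(function(l) ll(l, cc, dd))
    expected <- 2 * (l1 - l0)
    bc <- list(tree = NULL,
               edges = data.frame(parent = 7, child = 1:6, raw_changes = cc,
                                  duration = dd, corrected_changes = cc,
                                  excluded = FALSE, rate = cc / dd))
    class(bc) <- "branch_changes"
    rt <- rate_equality_tests(bc)
    expect_equal(rt$table$statistic[i], expected, tolerance = 1e-5)
  }
})

test_that("rate elevation on a clade is flagged high", {
  sim <- simulate_study(n_taxa = 30, n_characters = 150,
                        clade_rate_multiplier = 10, seed = 12)
  bc <- suppressWarnings(
    branch_rates(completeness_correct(fitch_optimize(sim$tree, sim$matrix),
                                      sim$matrix)))
  rt <- rate_equality_tests(bc)
  expect_lt(rt$global$p, 0.01)
  clade_tips <- names(sim$groups)[sim$groups == "clade_1"]
  in_clade <- vapply(seq_len(nrow(bc$edges)), function(e) {
    below <- sim$tree$tip.label[tips_below_for_test(sim$tree, bc$edges$child[e])]
    all(below %in% clade_tips)
  }, TRUE)
  expect_gt(sum(rt$table$flag == "high" & in_clade, na.rm = TRUE), 0)
})

test_that("branches contribute their rate to every overlapped interval", {
  tr <- ape::read.tree(text = "(A:10,B:2);")
  attr(tr, "node_ages") <- c(0, 8, 10)  # A spans 10-0, B spans 10-8
  bc <- list(tree = tr,
             edges = data.frame(parent = c(3, 3), child = c(1, 2),
                                raw_changes = c(5, 2), duration = c(10, 2),
                                corrected_changes = c(5, 2),
                                excluded = c(FALSE, FALSE),
                                rate = c(0.5, 1)))
  class(bc) <- "branch_changes"
  bins <- time_bins(c("old", "mid", "young"), start = c(12, 8, 4),
                    end = c(8, 4, 0))
  by_int <- rates_by_interval(bc, bins)
  expect_equal(by_int$old, c(0.5, 1))   # both branches overlap 12-8
  expect_equal(by_int$mid, 0.5)
  expect_equal(by_int$young, 0.5)
})

test_that("rate-time regression recovers trends and Kendall's tau", {
  bins <- time_bins(paste0("b", 1:5), start = seq(50, 10, -10),
                    end = seq(40, 0, -10))
  # one rate per interval, increasing with time before present -> tau = 1
  rates <- as.list(setNames(c(5, 4, 3, 2, 1), bins$label))
  r <- rate_time_regression(rates, bins)
  expect_equal(r$tau, 1)
  expect_gt(r$slope, 0)
  # constant rates: zero slope and tau
  rates0 <- as.list(setNames(rep(2, 5), bins$label))
  r0 <- rate_time_regression(rates0, bins)
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_true(is.na(r0$tau) || abs(r0$tau) < 1e-12)
})

test_that("Kendall tau equals brute-force pair counting", {
  set.seed(19)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(unname(cor(x, y, method = "kendall")), naive_kendall(x, y),
               tolerance = 1e-12)
})
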