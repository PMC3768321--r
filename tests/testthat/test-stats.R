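test_that("Mantel statistic is the correlation of the upper triangles", {
  d1 <- random_dist(10, seed = 1)
  d2 <- random_dist(10, seed = 2)
  ut <- upper.tri(d1)
  for (meth in c("spearman", "kendall", "pearson")) {
    m <- mantel_test(d1, d2, method = meth, nperm = 19, seed = 3)
    expect_equal(m$statistic, cor(d1[ut], d2[ut], method = meth),
                 tolerance = 1e-12)
  }
})

test_that("a matrix compared with itself gets the smallest attainable p", {
  d <- random_dist(12, seed = 5)
  m <- mantel_test(d, d, nperm = 199, seed = 7)
  expect_equal(m$statistic, 1)
  expect_equal(m$p, 1 / 200)
})

test_that("exact Mantel enumeration matches a hand enumeration at n = 5", {
  d1 <- random_dist(5, seed = 11)
  d2 <- random_dist(5, seed = 12)
  m <- mantel_test(d1, d2, method = "pearson", exact = TRUE)
  ut <- upper.tri(d1)
  enumerate <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(enumerate(v[-i]), function(rest) c(v[i], rest))))
  }
  null <- vapply(enumerate(1:5), function(p) {
    dp <- d2[p, p]
    cor(d1[ut], dp[ut])
  }, numeric(1))
  obs <- cor(d1[ut], d2[ut])
  expected_p <- sum(abs(null) >= abs(obs) - 1e-12) / length(null)
  expect_equal(m$statistic, obs, tolerance = 1e-12)
  expect_equal(m$p, expected_p, tolerance = 1e-12)
  expect_equal(m$n_permutations, factorial(5) - 1)
})

test_that("Mantel agrees with vegan on statistic and approximate p", {
  skip_if_not_installed("vegan")
  d1 <- random_dist(15, seed = 31)
  d2 <- 0.6 * d1 + 0.4 * random_dist(15, seed = 32)
  v <- vegan::mantel(as.dist(d1), as.dist(d2), method = "spearman",
                     permutations = 999)
  m <- mantel_test(d1, d2, method = "spearman", nperm = 999, seed = 1,
                   two_sided = FALSE)
  expect_equal(m$statistic, unname(v$statistic), tolerance = 1e-12)
  expect_lt(abs(m$p - v$signif), 0.05)
})

test_that("npMANOVA pseudo-F matches vegan::adonis2", {
  skip_if_not_installed("vegan")
  set.seed(41)
  sc <- rbind(matrix(rnorm(20), 5), matrix(rnorm(20, mean = 1.5), 5),
              matrix(rnorm(20, mean = 3), 5))
  rownames(sc) <- paste0("T", 1:15)
  groups <- setNames(rep(c("a", "b", "c"), each = 5), rownames(sc))
  r <- npmanova(sc, groups, nperm = 999, seed = 2)
  v <- vegan::adonis2(dist(sc) ~ g, data = data.frame(g = groups),
                      permutations = 999)
  expect_equal(r$statistic, v$F[1], tolerance = 1e-9)
  expect_lt(abs(r$p - v$`Pr(>F)`[1]), 0.05)
  # pairwise table carries Bonferroni-adjusted p-values
  expect_equal(nrow(r$pairwise), 3)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p - 1e-12))
  expect_true(all(r$pairwise$p_adj <= 1))
})

test_that("ANOSIM R matches vegan and hits 1 for separated clusters", {
  skip_if_not_installed("vegan")
  set.seed(51)
  sc <- rbind(matrix(rnorm(18, sd = 0.1), 6), matrix(rnorm(18, 5, 0.1), 6))
  rownames(sc) <- paste0("T", 1:12)
  groups <- setNames(rep(c("a", "b"), each = 6), rownames(sc))
  d <- as.matrix(dist(sc))
  r <- anosim_test(d, groups, nperm = 499, seed = 3)
  v <- vegan::anosim(as.dist(d), groups, permutations = 499)
  expect_equal(r$statistic, unname(v$statistic), tolerance = 1e-9)
  expect_equal(r$statistic, 1)
  # a permutation occasionally recreates the split, so p sits at a small
  # multiple of the attainable floor
  expect_lte(r$p, 0.01)
})

test_that("ANOSIM R stays near zero for random group labels", {
  set.seed(61)
  sc <- matrix(rnorm(60), 20)
  rownames(sc) <- paste0("T", 1:20)
  groups <- setNames(rep(c("a", "b"), 10), rownames(sc))
  r <- anosim_test(as.matrix(dist(sc)), groups, nperm = 999, seed = 4)
  expect_lt(abs(r$statistic), 0.25)
  expect_gt(r$p, 0.05)
})

test_that("Kruskal-Wallis and Mann-Whitney wrap the base implementations", {
  set.seed(71)
  a <- rnorm(12); b <- rnorm(10, 1); c <- rnorm(8, 2)
  kw <- kruskal_wallis(list(a = a, b = b, c = c))
  base_kw <- kruskal.test(list(a, b, c))
  expect_equal(kw$H, unname(base_kw$statistic))
  expect_equal(kw$p, base_kw$p.value)
  mw <- mann_whitney(a, b)
  base_w <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(mw$U, unname(base_w$statistic))
  expect_equal(mw$p, base_w$p.value)
})

test_that("rate group comparisons use log10 rates by default", {
  set.seed(81)
  groups <- list(g1 = 10^rnorm(15, 0), g2 = 10^rnorm(15, 1),
                 g3 = 10^rnorm(15, 2))
  r <- rate_group_tests(groups)
  manual <- kruskal.test(lapply(groups, log10))
  expect_equal(r$kruskal$H, unname(manual$statistic))
  expect_equal(nrow(r$pairwise), 3)
  expect_lt(r$kruskal$p, 0.01)
})

test_that("generalized differencing removes a linear trend exactly", {
  t <- 1:10
  series <- 3 + 2 * t
  gd <- generalized_differencing(series, t)
  expect_equal(as.numeric(gd), rep(0, 10), tolerance = 1e-9)
})

test_that("generalized differencing estimates small rho for white noise", {
  set.seed(91)
  rhos <- replicate(30, {
    x <- rnorm(40)
    attr(generalized_differencing(x, 1:40), "rho")
  })
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("generalized differencing recovers AR(1) autocorrelation", {
  set.seed(101)
  n <- 400
  rho_true <- 0.7
  x <- as.numeric(arima.sim(list(ar = rho_true), n))
  gd <- generalized_differencing(x, 1:n)
  expect_equal(attr(gd, "rho"), rho_true, tolerance = 0.12)
  # residuals of the differenced series lose their lag-1 correlation
  expect_lt(abs(cor(gd[-1], gd[-n])), 0.15)
  expect_error(generalized_differencing(1:3, 1:3), "4")
})

test_that("diversity-disparity correlation reports both coefficients", {
  t <- seq(250, 200, -5)
  disp <- seq(1, 11) + rnorm(11, sd = 1e-8)
  dd <- diversity_disparity_correlation(disp, disp, t)
  expect_equal(dd$estimate[dd$method == "pearson"], 1, tolerance = 1e-6)
  expect_equal(dd$estimate[dd$method == "spearman"], 1, tolerance = 1e-6)
  set.seed(111)
  a <- rnorm(11); b <- rnorm(11)
  raw <- diversity_disparity_correlation(a, b, t)
  gd <- diversity_disparity_correlation(a, b, t, differenced = TRUE)
  expect_equal(raw$estimate[raw$method == "pearson"], cor(a, b))
  expect_true(all(is.finite(gd$estimate)))
})

test_that("permutation p-values never fall below the add-one floor", {
  d1 <- random_dist(8, seed = 121)
  d2 <- random_dist(8, seed = 122)
  for (np in c(9, 99)) {
    m <- mantel_test(d1, d2, nperm = np, seed = 6)
    expect_gte(m$p, 1 / (np + 1))
    expect_lte(m$p, 1)
  }
})
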