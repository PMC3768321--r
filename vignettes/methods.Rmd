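---
title: "Methods: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodiv)
```

This vignette documents the statistical models implemented by
`morphodiv`, the default parameter values and why they were chosen, what
the synthetic-data generator does and does not emulate, and the
numerical and open-design decisions a user should know about before
interpreting results.

## 1. Distance model

`ged_matrix()` implements the generalized Euclidean distance for
cladistic matrices. For taxa $x, y$ and character $i$ with weight $w_i$,
the per-character difference is $\delta_i = |x_i - y_i|$ for ordered and
$\delta_i = 1\{x_i \neq y_i\}$ for unordered characters; polymorphic
cells contribute, by default, the *minimum* difference over their member
states (`polymorphism = "mean"` averages instead). Characters where
either taxon is unscored are *incomparable*; their squared differences
are imputed by the pair's weighted mean comparable squared difference,
giving

$$\mathrm{GED}(x,y) = \sqrt{S_{d^2} + (W - W_\mathrm{comp})\,
  S_{d^2} / W_\mathrm{comp}}$$

with $S_{d^2} = \sum_\mathrm{comp} w_i \delta_i^2$,
$W_\mathrm{comp} = \sum_\mathrm{comp} w_i$ and $W = \sum_i w_i$. The
imputation keeps all taxon pairs at a common (full) character weight, at
the cost of pulling poorly overlapping pairs toward the pair's average
dissimilarity. A pair with *no* jointly scored characters is an error,
deliberately: silently imputing the whole distance would fabricate data.

## 2. Ordination and disparity

`pco()` double-centres $-\tfrac12 d^2$ (Gower) and eigendecomposes it.
Because the GED is generally non-Euclidean, negative eigenvalues occur;
they are reported but **no correction** (Cailliez/Lingoes) is applied,
and scores use positive-eigenvalue axes only. The default of 20 retained
axes keeps the bulk of positive variance at study scale (~50 taxa) while
excluding the noisiest axes; requesting more axes than positive
eigenvalues truncates with a warning.

`disparity_indices()` returns sum and root-product of axis ranges
(morphospace extent) and of axis variances (spread about the centroid;
denominator $m-1$). Root-products are $k$-th roots computed in log
space; any zero axis zeroes them. `bootstrap_disparity()` resamples taxa
with replacement (default `n_reps = 1000`, enough for stable percentile
95% CIs at these group sizes) and can rarefy to a common $n$;
`disparity_by_group()` always adds a companion profile rarefied to the
smallest group, because range-based indices grow with sample size and
raw comparisons between unequal groups would be biased.

## 3. Morphospace clustering

`morphospace_clustering()` tests whether taxa clump in the space of the
first three axes using a three-dimensional Ripley's K,

$$\hat K(r) = \frac{V}{n(n-1)} \sum_{i \neq j} e_{ij}\,
  1\{d_{ij} \le r\},$$

with translation edge correction
$e_{ij} = V / \prod_a (L_a - |\Delta_a|)$ inside the observation box.
The box is the taxa's axis-aligned bounding box expanded 5% per side — a
compromise between clipping the pattern (0%) and diluting it with empty
space. The null is complete spatial randomness (CSR): `nsim = 999`
uniform simulations in the same box give a rank-1 (pointwise min/max)
envelope, and the pattern is called clustered where observed K exceeds
the upper envelope at any radius. Taking the extreme of 999 simulations
makes the pointwise level 0.2% two-sided; scanning all radii raises the
effective level, so the verdict should be read as exploratory, not as a
calibrated hypothesis test.

## 4. Time-scaling

`calibrate_tree()` dates nodes from first-appearance data (FADs):

- `basic`: node age = oldest descendant FAD; produces zero-length
  branches wherever a node and its oldest descendant coincide.
- `mbl` (default in the pipeline): after `basic`, ancestors are pushed
  older until every branch is at least `mbl` Myr long. The default
  `mbl = 1` Myr is small against typical stage durations, so it removes
  zero-length branches while minimally distorting ages.
- `equal`: zero-length branches borrow time from the subtending path,
  spreading it equally.

The root is placed `root_buffer = 2` Myr above the oldest FAD so the
earliest branch has positive duration. All three methods are
assumption-laden; rate analyses should be checked under more than one
calibration when branch durations matter.

## 5. Branch rates and rate tests

`fitch_optimize()` counts character changes per branch by unit-cost
Sankoff dynamic programming (equivalent to Fitch parsimony for unordered
characters; missing cells are fully ambiguous, polymorphic cells
ambiguous over their members). Ties between equally parsimonious
placements are resolved by `optimization`: ACCTRAN changes early
(rootward), DELTRAN late (tipward); residual ties break toward the
lowest state index, making results deterministic. Per-character change
totals equal the parsimony length under either convention.

`completeness_correct()` divides each branch's count by the fraction of
characters scorable on it (a character is scorable at a tip if coded
there, and at an internal node if coded in at least one descendant tip),
correcting the systematic undercount on poorly coded branches.
`branch_rates()` divides by branch duration; zero-rate and zero-duration
branches are flagged excluded *for log-rate analyses* (log10 of zero is
undefined).

`rate_equality_tests()` models branch counts as Poisson with mean
$\lambda_i t_i$ and compares a single-rate null against branch-specific
rates globally (df = branches − 1) and per branch against the pooled
rest (df = 1), flagging Benjamini–Hochberg-adjusted $p < 0.05$ as
`high`/`low`. Two deliberate choices:

- **Zero-change branches stay in the test.** Excluding them would
  zero-truncate the count distribution and destroy the null calibration
  of the LRT; only zero-duration and wholly unscorable branches are
  dropped.
- **Corrected counts are real-valued**, so the likelihood is evaluated
  with Gamma-function continuity (the $\log c!$ terms cancel in every
  ratio and are omitted).

**Limitation.** The Poisson null describes the *generating* process.
Counts reconstructed by parsimony are not Poisson: multiple hits
collapse, ACCTRAN/DELTRAN concentrate ambiguous changes, and restricting
matrices to variable characters induces dependence. In simulation, the
end-to-end false-positive rate of the global LRT under a homogeneous
generating rate is well above nominal, while the flagging machinery is
calibrated when its Poisson null actually holds (the package's
acceptance tests measure both power end-to-end and size at the count
level). Branch flags are therefore best treated as a ranking of
candidate branches, not as exact p-values — a caveat that applies to
this entire family of parsimony-based rate methods.

## 6. Permutation tests and time series

`mantel_test()`, `npmanova()` and `anosim_test()` permute labels with
the add-one rule, $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(\text{nperm} + 1)$, so $p$ can never be 0 and the tests are valid at
finite `nperm`. Defaults (999 for Mantel, 9999 for group tests) resolve
p-values to 0.001/0.0001 at modest cost. `mantel_test(exact = TRUE)`
enumerates all $n!$ permutations for $n \le 8$. npMANOVA's pseudo-F is
computed from pairwise squared Euclidean distances in score space with
Bonferroni-adjusted pairwise comparisons; ANOSIM uses mid-ranks for
ties.

`generalized_differencing()` removes a fitted linear trend and the lag-1
autocorrelation $\hat\rho$ of its residuals by quasi-differencing
(Prais–Winsten: first element scaled by $\sqrt{1-\hat\rho^2}$), so
diversity–disparity correlations are not driven by shared trend or
autocorrelation. It requires at least 4 points; $\hat\rho$ from few
time bins is noisy, which propagates into the differenced correlations.

## 7. The synthetic-data generator

`simulate_study()` produces a full analysis-ready dataset. What it
emulates, with defaults and rationale:

- **Tree**: birth–death (`ape::rphylo`) with `birth = 0.08`,
  `death = 0.03` per Myr — at ~50 tips this yields root ages around
  60 Myr, matching the temporal scale of a Permo-Triassic radiation.
- **Characters**: equal-rates Mk along each branch with
  `rate = 0.005` changes/Myr/character and state counts drawn from 2–5
  with probabilities 0.55/0.25/0.12/0.08 — a few changes per character
  over the tree, and the binary-dominated state spectrum typical of
  cladistic matrices. Invariant characters are resampled
  (`ensure_variable = TRUE`) because real matrices contain only variable
  characters; note this conditioning makes reconstructed counts
  slightly non-Poisson (see §5). `clade_rate_multiplier` elevates one
  clade's rate to create detectable heterogeneity.
- **Missing data**: each taxon's cells are masked independently at a
  per-taxon fraction drawn uniformly from 0.05–0.5, spanning
  well-coded to poorly coded fossils.
- **Ranges**: FAD = tip age plus an exponential preservation lag (mean
  2 Myr, truncated at the subtending branch's origin); the observed
  duration is exponential (mean 2 Myr). This emulates incomplete
  preservation, not any particular facies or sampling model.
- **Groups and bins**: the tree is split into a basal array and two
  derived clades; `n_bins = 11` equal-length bins cover the realized
  ranges.

What it does **not** emulate: correlated character evolution, ordered
characters, directional (Dollo-like) change, taxonomic practice
(synonymy, wastebasket taxa), geographically structured sampling, or
character-rate heterogeneity within a clade. Conclusions about those
phenomena cannot be validated with this generator.

## 8. Numerical choices

- Eigendecomposition uses `eigen(symmetric = TRUE)`; axis signs are
  arbitrary, and all downstream statistics are sign-invariant (verified
  by tests).
- Ripley's K uses a sort-and-count (`findInterval`) formulation, exact
  against the naive double loop to 1e-10.
- Zero-length terminal branches get an `epsilon = 1e-6` Myr floor (with
  a warning) in Brownian ancestral estimation, which otherwise divides
  by branch length.
- Sub-seeds for independent stochastic stages are derived as
  `(seed + 1009 k) mod (2^31 - 1)`, keeping every seed a valid 32-bit
  integer; seeded code runs in a local RNG scope and restores the
  caller's RNG state.
- The add-one permutation rule bounds all permutation p-values away
  from zero.

## 9. Open design points

- Time bins: `cynodont_bins()` anchors an 11-bin Permo-Triassic to
  Jurassic scheme at the Permo-Triassic boundary (252 Ma);
  `cynodont_rate_bins()` pools the youngest intervals where branch
  counts get sparse. Users with different stratigraphic resolutions
  should supply their own `time_bins()`.
- Polymorphism handling (`min` vs `mean`) and Mantel coefficient
  (Spearman default; Kendall and Pearson available) are exposed because
  the literature is not uniform; defaults follow the most common
  practice.
- The clustering verdict's envelope rank, box expansion and axis count
  are exposed parameters; the defaults (999 simulations, 5%, 3 axes)
  are conventional, not optimal in any formal sense.

## 10. Summary of limitations

1. GED imputation biases distances of poorly overlapping taxon pairs
   toward the mean; interpret ordinations of very incomplete matrices
   cautiously.
2. Negative PCo eigenvalues are discarded, so score-space distances
   slightly understate the original dissimilarities.
3. Parsimony-based branch counts are biased low on long branches and
   the rate LRT is anticonservative end to end (§5).
4. Time-scaling from FADs alone ignores stratigraphic uncertainty;
   `mbl`/`equal` redistribute time by convention, not by inference.
5. The CSR clustering envelope is exploratory (multiple radii, rank-1
   envelope).
6. The generator's homogeneous Mk model is a validation tool, not a
   faithful model of morphological evolution.
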