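---
title: "Generative imputation with adversarial random forests: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative imputation with adversarial random forests: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfimpute)
```

## The problem

Incomplete tables are the norm in biostatistical practice. Deleting
incomplete rows loses power and, outside of missing-completely-at-random
(MCAR) settings, biases estimates; filling cells with column means or medians
distorts variances and relationships; and single "best-guess" imputation of
any kind understates uncertainty, producing confidence intervals that are too
narrow. Multiple imputation addresses the last problem by producing $m$
completed tables whose variation reflects what is actually unknown about the
missing cells, at the price of (usually) $m$ times the computation.

`arfimpute` takes a generative view: learn the joint distribution of the data
with a tree-ensemble density estimator, then impute each incomplete row from
the conditional distribution of its missing entries given its observed ones.
Because the fitted model *is* the conditional distribution, drawing one
completion or twenty costs the same single training run.

## The model

### Adversarial training

An adversarial random forest (ARF) learns a density through a
discriminator loop:

1. Build a naive synthetic table by bootstrapping each column independently
   — a draw from the product of the marginals.
2. Grow a random-forest classifier to distinguish real rows (label 1) from
   synthetic rows (label 0).
3. If the forest's out-of-bag (OOB) accuracy is below $0.5 + \delta$, stop:
   real and synthetic are indistinguishable. Otherwise regenerate the
   synthetic table by bootstrapping each column independently *within each
   leaf* of the current forest — synthetic data that already respects the
   dependence structure the forest found — and repeat.

At convergence the forest can no longer detect any dependence the generator
misses, which motivates treating features as mutually independent *within*
each leaf (local independence). Each leaf $\ell$ is a hyperrectangle
$\mathcal{X}_\ell$ (the conjunction of its root-to-leaf split conditions)
carrying weight $\omega_\ell = n_{t\ell} / (T\,n_t)$, the share of real rows
it contains, averaged over the $T$ trees. The density estimate is the mixture

$$\hat p(x) \;=\; \sum_{\ell} \omega_\ell \prod_{j=1}^{p}
  \hat p_{\ell j}(x_j),$$

with univariate leaf densities $\hat p_{\ell j}$: a maximum-likelihood
Gaussian truncated to the leaf interval for continuous features, and a
multinomial over the admissible levels for categorical ones. Leaves whose
bounds exclude $x$ contribute zero because the truncated densities vanish
outside their support.

### Missing values during training: MIA splits

The discriminator must be trainable on data that itself contains `NA`. We use
missingness-incorporated-in-attributes (MIA) splits: for a numeric feature
and each candidate threshold $s$, both "$x_j \le s$ *or* `NA`" versus
"$x_j > s$" (split A) and "$x_j \le s$" versus "$x_j > s$ *or* `NA`"
(split B) are scored, and the Gini-optimal assignment wins; for categorical
features `NA` is simply an additional level. Missingness thus becomes
informative structure rather than an obstacle, and every row — even an
all-`NA` row — routes to exactly one leaf per tree.

Candidate thresholds are the observed values themselves ($x \le s$ with $s$ a
data value). This matters for MIA: separating all observed values from the
`NA` group requires a cut at the maximum observed value, which a
midpoint-only candidate set cannot express.

### Conditioning and imputation

For a row with observed entries $x_C$ and missing entries $x_{\bar C}$,
Bayes' rule and local independence give the conditional mixture

$$\hat p(x_{\bar C} \mid x_C) = \sum_\ell \tilde\omega_\ell
  \prod_{j \in \bar C} \hat p_{\ell j}(x_j),
  \qquad
  \tilde\omega_\ell \propto \omega_\ell \prod_{j \in C}
  \hat p_{\ell j}(x_j),$$

with $\tilde\omega$ normalized to sum to one. Leaves incompatible with the
evidence get exactly zero weight. Imputation is then:

* **Single imputation (default):** continuous cells receive the conditional
  expectation $\sum_\ell \tilde\omega_\ell \mu_{\ell j}$, where
  $\mu_{\ell j}$ is the leaf's *empirical* mean of real non-missing values
  (not the truncated-Gaussian mean — both are available, the empirical mean
  is the default); categorical cells receive the level maximizing
  $\sum_\ell \tilde\omega_\ell \hat p_{\ell j}(\text{level})$.
* **Multiple imputation:** each of the $m$ completions draws **one fresh
  leaf per row** from $\tilde\omega$ and samples every missing feature from
  that leaf's distributions. Sampling a single leaf per row preserves the
  dependence among several missing entries of the same row through the leaf
  identity; redrawing the leaf for every completion is what creates
  between-imputation variability without refitting anything.

```{r example}
set.seed(1)
n <- 100
d <- data.frame(x1 = c(rnorm(n, -1, 0.1), rnorm(n, 1, 0.1)),
                x2 = c(rnorm(n, 1, 0.1), rnorm(n, -1, 0.1)))
fit <- arf(d, num_trees = 50, seed = 1)
fit
# conditioning on the first cluster's x1 recovers its x2 center
conditional_expectation(fit, list(x1 = -1), "x2")
```

## Tunable parameters

| Parameter | Default | Meaning and guidance |
|---|---|---|
| `num_trees` | 100 | Discriminator forest size. More trees smooth the mixture; 100 matches common forest practice. |
| `min_node_size` | 10 | Minimum in-bag rows per leaf (on the stacked 2n-row table). Larger values give wider leaves, hence more diverse imputations — worth raising under heavy missingness. |
| `delta` | 0 | Convergence slack: training stops when OOB accuracy < 0.5 + `delta`. 0 is the strictest sensible choice. |
| `max_iters` | 10 | Cap on adversarial rounds; non-convergence returns the best round with a warning. In practice 1–3 rounds suffice. |
| `mtry` | `floor(sqrt(p))` | Features tried per split, standard forest default. |
| `m` | 20 | Number of multiple imputations; costs no extra training. |
| `alpha` | 0 | Pseudo-count for categorical leaf frequencies. |

## Numerical choices

* **Weights in log space.** Products of many observed-feature densities
  underflow; adjusted weights are accumulated as log-densities and
  normalized by log-sum-exp.
* **Truncated-Gaussian MLE.** No closed form exists under truncation; we
  maximize the likelihood over $(\mu, \log\sigma)$ with Nelder–Mead started
  at the sample moments, with the closed form used when both bounds are
  infinite. The truncated likelihood is flat or divergent for thin leaves
  (a handful of points that look uniform on their interval can push
  $\hat\sigma \to \infty$), so estimates outside a trust region — $\sigma$
  above twice the global marginal SD, or $\mu$ more than 4 SD from the leaf
  mean — fall back to the leaf's sample moments.
* **Degenerate leaves.** A leaf whose values of feature $j$ are all equal
  gets $\hat\mu = c$ and $\hat\sigma$ floored at $10^{-6}$ times the
  marginal SD ($10^{-9}$ absolute if that SD is zero), keeping the density
  proper. A leaf with a *single* observation inherits the global marginal SD
  instead — one point carries no scale information, and a near-point-mass
  there would distort generation. A leaf with *no* real non-missing values
  of $j$ inherits the global marginal distribution truncated to its bounds.
* **Interval convention.** Numeric splits produce left $=(lo, s]$, right
  $=(s, hi]$, mirroring $x_j \le s$ vs $x_j > s$; per tree the leaf
  intervals partition feature space, so exactly one leaf covers any complete
  row.
* **Ties.** Equal-impurity splits resolve to the lowest feature index, then
  the smallest threshold, then split A before split B; equal categorical
  mode scores resolve to the earlier declared level. All randomness flows
  through R's RNG, so a seed makes training, generation and imputation
  bit-reproducible.
* **Zero-mass evidence.** If no leaf is compatible with a row's observed
  values (possible for out-of-range evidence under bounded leaves), the
  unadjusted weights are used and the row is flagged — imputation always
  produces a value.
* **Serialization.** Models round-trip through JSON with 17 significant
  digits; anything coarser can flip a threshold comparison, because
  thresholds are exact data values.

## Design choices that were genuinely open

* **Which forest to return.** "Stop when OOB accuracy drops below
  $0.5+\delta$" leaves open whether the returned model is the last
  distinguishing forest or the first indistinguishable one. We return the
  first forest whose OOB accuracy is below the threshold — the local
  independence argument applies to the discriminator that can no longer
  tell real from synthetic — and record the full accuracy history so the
  alternative remains recoverable.
* **Missing markers in synthetic data.** Naive and leaf-wise synthesis draw
  `NA` cells like any other cell, so each synthetic column preserves its
  missingness rate. Otherwise the discriminator would separate the classes
  on missingness alone and never converge.
* **Leaf counts.** All real rows are routed down every tree when harvesting
  leaves ($n_t = n$), so $\sum_\ell \omega_\ell = 1$ exactly and leaf
  distributions use all available real data; the per-tree bootstrap is kept
  only for the OOB convergence statistic.
* **Eq.-style conditional mean.** The conditional expectation uses the
  leaf's empirical mean rather than the mean of the fitted truncated
  Gaussian; both are stored.

## The simulation benchmark

The built-in harness emulates a copula-based benchmark design:

* **Features.** A latent multivariate normal with Toeplitz correlation
  $0.5^{|i-j|}$ is pushed through the standard normal CDF and the inverse
  CDF of one of five marginals: N(0,1), Bernoulli(0.5), Poisson(2),
  Gamma(2, 0.5), Uniform(−1, 1).
* **Outcome.** $y_i \sim \text{Bernoulli}(\sigma(x_i\beta))$ (linear) or
  $\sigma(x_i^2\beta)$ (squared), with equidistant effects
  $\beta = (-0.5, \dots, 0.5)$.
* **Amputation.** Odd-indexed columns lose exactly $\mathrm{round}(\rho n)$
  cells each: uniformly (MCAR), in rows on a randomly chosen side of the
  *right-neighbor* column's median (MAR; the neighbor is the most
  correlated fully observed feature under the Toeplitz structure), or of
  the column's own median (MNAR). Rows at the median count as the lower
  side; if the chosen side is too small through ties (discrete marginals),
  deletions spill into tied rows at random. Exact counts rather than
  per-cell Bernoulli deletion fix the missingness proportion by design.
* **Scoring.** Single imputation is scored by NRMSE — both tables
  standardized by the *original* table's column means and (n−1) SDs, then
  the root mean square over the deleted cells — and by the Brier score of a
  downstream logistic regression fitted to the imputed training table and
  evaluated on the imputed test table. Multiple imputation is scored by
  Rubin's rules: pooled estimate $\bar\beta$, total variance
  $\bar W + (1+1/m)B$, classical degrees of freedom
  $(m-1)(1 + \bar W/((1+1/m)B))^2$ (normal quantile when $B = 0$; the
  Barnard–Rubin small-sample correction is deliberately not applied), then
  coverage rate, mean CI width and coefficient RMSE across replicates.
  Bernoulli features are categorical inside the ARF but numeric 0/1 in the
  NRMSE and the regressions.

The NRMSE is reported over the deleted cells; since observed cells pass
through imputation unchanged, normalizing over all $n\,p$ cells differs only
by the factor $\sqrt{n p / |\text{deleted}|}$ — `nrmse()` computes the
all-cells version by default and the deleted-cells version when given the
missingness mask, which is what the benchmark reports (random imputation
then scores $\approx \sqrt 2$ under MCAR with standardized data, a useful
sanity anchor).

What the generator does *not* emulate: real covariate distributions with
mixed scales and rare levels, structured (e.g. monotone or block)
missingness, and outcome models beyond the logistic family. Passing the
benchmark therefore shows calibration under a known, well-behaved
data-generating process, not performance on any particular applied dataset.

## Problem sizes in the shipped tests

The published design this harness emulates spans 5 marginals × 3 dimensions
× 3 sample sizes × 3 patterns × 3 rates × 2 effects × 1000 replicates —
far more than a package test should run. The package's own acceptance tests
use two miniatures chosen to span the dimensions each quantity is actually
driven by: all five marginals and $p \in \{4, 10, 20\}$ (MAR, rate 0.2,
$K{=}1$) for the single-imputation scores, and the unit-order-variance
marginals with $n \in \{500, 1000\}$ (MCAR, rate 0.2, $K{=}20$, $m{=}20$)
for the inference metrics. At that scale the expectation-mode NRMSE, the
downstream Brier score, the ~95% coverage and the coefficient RMSE reproduce
the published aggregate levels; the median CI width does not — it is
dominated by $n$ and by the marginals' feature variances, and its published
level is attainable only as the median over the full grid (the
complete-data width at $n{=}500$ under the normal marginal is already 0.44).
The corresponding test asserts the published level and is expected to fail
at the miniature scale; the numbers it prints make the gap and its source
visible.

## Limitations

* Generative tree ensembles blur fine structure in high dimensions; in the
  emulated design the method is strongest at low to moderate $p$.
* Under heavy missingness the conditional mixtures concentrate on few
  leaves, and multiple-imputation variability can run low (intervals on the
  narrow side); raising `min_node_size` widens the leaves and counteracts
  this.
* Point evidence only: conditioning on intervals or on external constraints
  is out of scope, as are per-cell conditional quantiles.
* Skewed marginals with squared outcome effects are hard for every imputer
  in this family; expect degraded coverage there.
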