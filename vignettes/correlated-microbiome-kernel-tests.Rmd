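---
title: "Kernel association tests for correlated microbiome data: models and methods"
author: "glmmkat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel association tests for correlated microbiome data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Family-based and longitudinal microbiome studies collect repeated
measurements per cluster (a family, a subject followed over time), so the
trait values within a cluster are correlated and methods that assume
independent samples inflate their type I error — drastically so at high
within-cluster correlation. At the same time, the community is
high-dimensional (hundreds to thousands of OTUs, `p >> n`), sparse, and
structured by a phylogeny, which makes per-OTU fixed-effect testing
hopeless. `glmmkat` addresses both problems at once: the within-cluster
correlation is absorbed by the random effects of a generalized linear
mixed model (GLMM), and the community enters the model through a
similarity kernel built from an ecological distance, reducing the
`p`-dimensional effect to a single variance component.

## Model

For measurement `j` in cluster `i`, with trait `y_ij`, covariates `x_ij`,
and OTU vector `z_ij`,

```
g(mu_ij) = x_ij' alpha + s_ij' v_i + h(z_ij),
```

with a canonical link `g` (identity, logit or log for Gaussian, Binomial
and Poisson traits). The random effect `v_i` is either a random intercept
(`s_ij = 1`, `v_i ~ N(0, sigma_g^2)`) or an independent random intercept
and slope (`s_ij = (1, t_ij)'`). The microbiome term `h` lives in the
reproducing-kernel Hilbert space of a kernel `kappa`; stacking the
measurements, the vector `delta = (h(z_ij))` is modelled as a random
effect with covariance `tau K`, where `K` is the N x N kernel matrix.
The community-trait association reduces to `H0: tau = 0`.

Each candidate kernel comes from an ecological distance matrix `D` by
Gower double-centering of the squared distances,

```
K = -1/2 (I - 11'/N) D^2 (I - 11'/N),
```

and negative eigenvalues (ecological distances need not be Euclidean) are
clamped to zero so `K` is a valid similarity matrix. Clamping — rather
than, say, taking absolute values — leaves Euclidean-embeddable distances
untouched and preserves the similarity interpretation; it can be disabled
with `psd = FALSE`. Five candidate distances are built in: binary Jaccard
and unweighted UniFrac (incidence only, sensitive when associated OTUs
are rare), Bray-Curtis and weighted UniFrac (full abundance, sensitive
when they are abundant), and generalized UniFrac with exponent
`theta = 0.5`, which interpolates between the two UniFrac extremes. The
UniFrac family uses the rooted phylogeny; the package computes all
variants from per-edge cumulative relative abundances, so they are
library-size invariant by construction, and Bray-Curtis is computed on
counts as given (rarefy first when depths differ).

## Null fit and score statistic

The null model (no microbiome term) is fitted by REML. For Gaussian
traits this is an exact linear-mixed-model fit; for Binomial and Poisson
traits the package iterates penalized quasi-likelihood (PQL): the working
response `y* = eta + (y - mu) g'(mu)` is refitted by weighted REML until
the fixed effects and variance components change by less than `1e-6`
(at most 100 iterations; non-convergence is an error that carries the
iteration trace). The dispersion is estimated for Gaussian traits and
fixed at 1 otherwise; variance components are floored at `1e-8` so the
marginal covariance stays invertible. The internal REML solver profiles
the residual scale and optimizes the variance components on the log scale
(Brent for one component, Nelder-Mead for two), with all cluster-block
algebra done through the Woodbury identity and `rowsum()` aggregation —
a criterion evaluation is O(N). The test suite checks the Gaussian path
against `lme4` and the PQL path against a dense-matrix reference
implementation.

The score statistic for `H0: tau = 0` is the quadratic form

```
Q(h) = (y* - X alpha)' V^-1 K_h V^-1 (y* - X alpha),   V = Sigma + W,
```

the reduced form of the variance-component score: its constant scale
factor and additive trace term do not affect permutation ranks, so they
are dropped. `W` is the working-error variance `diag(phi)` (Gaussian),
`diag(1/(mu(1-mu)))` (Binomial) or `diag(1/mu)` (Poisson). A published
description of this statistic states `W = I` for Binomial and Poisson
traits; because that conflicts with the quasi-likelihood derivation the
working variance is the default here, and `w_matrix = "identity"`
reproduces the literal convention — permutation inference is valid under
both, and the choice moves empirical rates by well under a point in our
checks.

## Permutation inference

P-values are semi-parametric: the null GLMM is fitted once, and the
working residual `r = V^-1(y* - X alpha)` is permuted. Only exchangeable
clusters may swap places: clusters with the same number of measurements
(random-intercept model), or the same size and time vector
(random-slope model). Under the intercept model, measurements are also
shuffled within every cluster (compound symmetry makes them
exchangeable); under the slope model within-cluster order is preserved,
so a slope design with no two clusters sharing a size and time vector
has a degenerate permutation null and is rejected with an explicit
error. Permuting `r` rather than refitting per permutation keeps the
cost at one fit plus `B` quadratic forms; `Q` is symmetric in `r` and
`K`, and the within-block entries of `r` are exchangeable under the
null.

With `B` permutations, the per-kernel p-value is
`(1 + #{Q_b >= Q_obs}) / (1 + B)` — ties count, and the estimate never
reaches zero. The adaptive omnibus statistic is the minimum per-kernel
p-value; its null distribution comes from the same permutations, with
each permuted statistic converted to a within-permutation rank-based
p-value (`#{b': Q_b' >= Q_b} / B`, ties conservative), so kernel
correlations are preserved at O(B) cost. One shared permutation stream
serves all kernels. When calibrating rejection rates at level `alpha`,
choose `B` so that `(B + 1) * alpha` is an integer (199, 399, 499, 999);
otherwise the discrete p-value support makes the test strictly
conservative at that level.

A `method = "naive"` mode fits an ordinary GLM null and permutes all `N`
residuals freely. It exists as a comparator only: on clustered data it
inflates the type I error (to above 70% in our high-correlation Gaussian
checks, versus ~5% for the mixed-model test on the same replicates).

## The synthetic study generator

`simulate_study()` reproduces a complete correlated-microbiome study
design so the operating characteristics are checkable without external
data:

* **Counts.** Dirichlet-multinomial draws over `p = 856` OTUs at 10,000
  reads per measurement. The community profile is a frozen package
  fixture: log-normal mean proportions (`sdlog = 2`, a realistic
  heavy-tailed abundance profile) with dispersion 0.02, plus a matching
  random-coalescent phylogeny, all generated deterministically from a
  fixed internal seed. A real estimated profile is not shipped;
  calibration and the kernel-ordering behaviour are robust to the
  profile, but absolute power levels are not transferable to any
  specific real community.
* **Within-cluster relatedness.** Measurements 2..m of each cluster are
  sequentially averaged with their already-updated predecessor,
  `Z_ij <- (Z_i(j-1) + Z_ij)/2`, rounding half-integers to even to keep
  counts integral.
* **Covariates and trait.** A cluster-level Bernoulli(0.5) covariate, a
  measurement-level confounder `0.5 scale(sum_A z) + N(0,1)` built from
  the associated OTU set `A`, and the trait
  `g(E y) = 0.5 scale(x1 + x2) + beta scale(sum_A z) + s'v`. `scale()`
  standardizes across all N measurements of a replicate. The set `A` is
  drawn even under `beta = 0` because the confounder requires it.
* **Scenarios.** `A` holds 50 OTUs drawn from the lower abundance half
  (P1), all OTUs (P2), the upper half (P3), or one of ten PAM clusters
  of the tree's cophenetic distances (P4, cluster chosen uniformly per
  replicate).
* **Designs.** Cluster counts n = 20 (sizes 2x7, 4x7, 3x6) or n = 50
  (2x17, 3x17, 4x16); random-effect variances 1/2, 1, 3/2, giving
  Gaussian intra-cluster correlations 1/3, 1/2, 3/5 under the intercept
  model; the slope model uses `t_ij = j` with independent intercept and
  slope variances.

## Experiment scales and what the checks show

The packaged operating-characteristic tests run at desk scale: the
calibration grids use 400 replicates per cell at `B = 199` (tolerance: 3
binomial standard errors at that replicate count), the power-ordering
comparisons 600–1,200 replicates at `B = 399` with a shared
per-replicate seed bank so all comparisons are paired, and the
acceptance script 1,000–2,000 replicates per cell at `B = 499`. The
reference design behind these rates used 30,000 replicates per
calibration cell; `run_type1_experiment()` / `run_power_experiment()`
accept any `reps`/`B` for larger runs.

Two power properties of the published narrative are only partly
reproduced under the synthetic community, and deliberately left visible
in the test suite rather than papered over. First, the min-p omnibus
trails the best single kernel by more than 10 points in the
abundant-OTU scenario P3 (~14 points; only Bray-Curtis is strongly
powered there, so the adaptive test pays the full multiplicity cost of
four uninformative kernels). Second, weighted UniFrac and Bray-Curtis
are statistically tied in the phylogenetic scenario P4, because the
PAM-selected OTU cluster also carries a strong abundance signal under
the log-normal profile. Both are properties of the fixture community,
not of the test machinery; with more strongly correlated kernels (as in
real communities with tight phylogeny-abundance coupling) the adaptive
test tracks the best kernel more closely. Likewise the power decrease
with growing random-effect variance is present but small (~5 points)
at the fixture's moderate power levels.

## Degenerate inputs and numerical choices

Zero-total measurements are rejected before any distance computation
(with the offending measurement named); unrooted trees or trees without
branch lengths are rejected for UniFrac; edges absent from both
measurements of a pair are excluded from every UniFrac sum; binary
traits that are all equal are rejected as degenerate; covariate matrices
must be full rank with a leading intercept column; rows must arrive
grouped by cluster (block structure is validated, not silently
reordered). PSD clamping uses a relative tolerance of `1e-10`; an
already-PSD kernel is returned unchanged. PCoA drops non-positive
eigenvalue axes and errors when more than `N - 1` axes are requested.

## Limitations

Crossed or nested multi-level random effects, non-canonical links,
zero-inflation in the count model, analytic (Davies-type) p-values, and
small-sample kurtosis adjustments are out of scope. PQL is known to
shrink variance components for binary traits with small clusters — the
permutation calibration absorbs this for testing purposes, but the
reported `sigma_g^2` for Binomial traits should not be read as an
unbiased estimate. The slope-model permutation scheme requires a design
with enough same-size, same-time clusters; severely unbalanced
longitudinal designs should use the intercept model.
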