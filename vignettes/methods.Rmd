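---
title: "Models and methods behind gradeshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradeshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradeshift)
```

# The scientific problem

Comparative neuroanatomy often asks whether a brain structure is enlarged in
some clades *relative to* an allometrically related structure, and whether
such enlargements arose once or repeatedly. gradeshift packages the full
analysis chain for this kind of question: a log-log allometry between two
volumes is fitted by phylogenetic GLS; its residuals become the
"reorganization" trait; shifts in that trait's adaptive optimum are located
by a Bayesian reversible-jump multi-regime Ornstein-Uhlenbeck (OU) sampler;
candidate grades are confirmed by phylogenetic ANCOVA; evolutionary history
and lineage rates come from a multiple-variance Brownian-motion (mvBM)
estimator compared against a generation-scaled neutral null; and rates of
two traits are compared by the distance-based (Q-mode) estimator.

# PGLS with Pagel's lambda

The regression model is $y = Xb + \epsilon$ with
$\epsilon \sim N(0, \sigma^2 V(\lambda))$, where $V(\lambda)$ has shared
root-to-tip path lengths off the diagonal, scaled by $\lambda \in [0, 1]$,
and unscaled root-to-tip depths on the diagonal. $\lambda = 1$ is Brownian
covariance, $\lambda = 0$ a star phylogeny. $\lambda$ is estimated by
maximizing the profile likelihood on a 1001-point grid followed by Brent
refinement, so the reported value is a global optimum of that scheme;
`nlme::gls(correlation = corPagel(...))` reproduces our estimates to four
decimals on interior optima (our $\lambda$ is clamped to $[0,1]$, corPagel
is not). Confidence intervals use GLS standard errors with $t$ quantiles on
$n - p$ degrees of freedom. The overall regression $F$ compares the fitted
model to the intercept-only model, both whitened under the fuller model's
$\hat\lambda$; using one covariance for both nested fits keeps $F$
non-negative and makes the nested-RSS statistic equal the Wald statistic
exactly, which the package exploits as an internal cross-check (both code
paths are computed and compared in the tests).

Relative size is the GLS residual of one log-volume on the other, reported
both in log units and as observed/predicted ratios on the antilog scale
($10^{\text{obs}-\text{pred}}$; volumes are log10-transformed once at load
time — the base is conventional and configurable).

# Phylogenetic ANCOVA

Grade structure enters the design as indicator columns for every non-control
group; the test statistic is
$F = \frac{(RSS_0 - RSS_1)/\Delta p}{RSS_1/(n - p_1)}$ with both residual
sums of squares computed in the $V(\hat\lambda)$-whitened space,
$\hat\lambda$ estimated on the fuller model. "Treatment groups versus a
control" comparisons are expressed by giving the null model a coarser
grouping (e.g. the two planted grades pooled). The slope test keeps group
intercepts in *both* nested models: without them, intercept differences
masquerade as slope heterogeneity and the equality-of-slopes assumption
cannot be assessed on its own. Type-I error of the intercept test is
calibrated: over 1000 constant-rate Brownian replicates with random
groupings, rejection at $\alpha = 0.05$ falls in $[0.03, 0.07]$ (asserted in
the test suite).

# Multi-regime OU model and the reversible-jump sampler

Trait evolution follows
$dX(t) = \alpha[\theta - X(t)]\,dt + \sigma\,dB(t)$, with the optimum
$\theta$ constant within a regime. A regime painting is induced by a set of
shift branches: every branch inherits its parent's regime unless a shift
starts on it. The expected tip value is a weighted sum of the optima along
the tip's root path with the classic exponential-integral weights; under the
default stationary root the weights sum to one. The tip covariance
conditional on the root is
$\frac{\sigma^2}{2\alpha} e^{-\alpha d_{ij}} (1 - e^{-2\alpha s_{ij}})$
(shared time $s_{ij}$, patristic separation $d_{ij}$); the stationary-root
variant drops the bracket. The likelihood is evaluated by Cholesky
factorization; a numerically non-positive-definite covariance returns a
$-10^{300}$ sentinel so the sampler treats it as a rejection instead of
crashing.

The reversible-jump sampler moves through shift configurations with
birth/death/relocate moves plus scalar updates of one optimum, $\alpha$, and
$\sigma^2$ (move probabilities 0.15/0.15/0.10/0.30/0.15/0.15, chosen for
mixing). The prior on the shift count is a conditional Poisson truncated to
$[0, n_{\text{tips}}/2]$ with mean one shift per 20 tips by default;
given the count, configurations are uniform over branch subsets. Births
draw the new optimum from a Gaussian centred on the parent regime's optimum;
because the proposal is a direct parameter draw, the acceptance ratio
carries the prior/proposal density ratio and the Jacobian is 1. With the
likelihood held constant the sampler reproduces the truncated-Poisson
shift-count prior (chi-square goodness of fit asserted in the tests), which
exercises the full trans-dimensional acceptance arithmetic. Scalar
parameters use log-scale random walks under weakly informative lognormal
priors centred on the data's Brownian rate and on a half-life of a quarter
of the tree depth — empirical centring that sets the scale, not the answer.
The first 20% of the chain is discarded; every `thin`-th state is retained;
the cached likelihood is recomputed from scratch every $10^4$ iterations and
the run aborts on drift. Per-branch shift support is the fraction of
retained samples containing a shift on that branch (PP), flagged at the
conventional 0.2 / 0.5 / 0.8 thresholds.

Effect size is summarized by the signal-to-noise ratio
$\eta_\phi = \frac{\min_{i \ne j} |\theta_i - \theta_j|}
{\sqrt{\sigma^2/2\alpha}} \,\phi$, where $\phi = 1 - e^{-\alpha \bar t}$
discounts by the adaptation attained over the mean root-to-tip depth
$\bar t$. The discount factor admits several definitions in the literature;
the decomposition (separation, stationary SD, $\phi$) is therefore returned
alongside the ratio so an alternative discount can be substituted without
re-running anything.

# mvBM ancestral states and lineage rates

Standard-BM ancestral states are the conditional means of the
tree-structured Gaussian model given the tips (equivalently, the values
minimizing summed squared change per unit branch length); they match
`phytools::fastAnc` to $10^{-8}$. The mvBM estimator relaxes the
constant-rate assumption with per-branch rate multipliers estimated as
follows: each branch's squared estimated change is standardized by the
*exact* variance of that estimate under the input branch lengths (so the
statistic is $\chi^2_1$ under constant-rate BM), smoothed over the branch's
immediate neighborhood (half own signal, half neighborhood mean), and
shrunk toward 1 with weight `shrink` (default 0.3); branch lengths are
rescaled by the resulting multipliers (total tree length fixed) and states
are re-estimated until stable. Two design points deserve emphasis. First,
standardizing by $\sigma^2 \ell$ instead of the exact estimator variance
drives lengths of low-change branches to zero, and iterating an exactly
standardized statistic to its fixed point makes the multipliers a drifting
random walk — both failure modes we observed and avoided by anchoring the
standardization to the input lengths. Second, recovery of a single
fast-evolving branch is intrinsically limited: the realized change on one
branch is a single $\chi^2_1$ draw, so even a 25-fold rate increase
produces a small change roughly a quarter of the time, and no estimator can
rank such a branch first. The tests therefore assert recovery of the
maximum multiplier on the planted branch *averaged* over replicate traits,
plus a majority-rank check per replicate.

Lineage rates are assessed against a neutral null: the tree is rescaled to
generations (each branch divided by the generation time of its descendant
node; missing species inherit the value of the patristic-closest known
species, ties broken lexicographically; internal nodes take their closest
descendant tip's value), constant-rate BM is simulated at a user-supplied
per-generation rate (a required input — it must come from data external to
the tree), and each branch's observed |change| is divided by the mean
simulated |change| (default 100 replicates). Simulated replicates are
re-estimated with the same ancestral-state method as the observed data;
mixing estimators (mvBM for the observed data, plain BM for the null)
biases the ratios downward by ~30%. Note the distributional fact that the
*median* per-branch ratio sits near 0.85 even under perfect
self-consistency — the observed change is one half-normal draw and its
median is below its mean — so calibration checks use the across-branch
mean, which is centred at 1.

# Q-mode rate comparison

A trait's Brownian rate is
$\hat\sigma^2 = (y - \hat a \mathbf 1)^\top C^{-1} (y - \hat a \mathbf 1)/n$
with $\hat a$ the GLS phylogenetic mean. The package carries two
algebraically identical implementations — a Cholesky quadratic form
(R-mode) and an inverse-square-root whitening (Q-mode) — and the tests
assert agreement to $10^{-10}$; the distance-based formulation is the one
that generalizes to high-dimensional traits. Rate equality between two
traits is tested by simulating `nsim` (default 999) bivariate constant-rate
BM datasets at the pooled rate, preserving the observed evolutionary
correlation between the traits (estimated from GLS cross-products), and
comparing the observed max/min rate ratio with the null ratios using the
add-one p-value $(\#\{null \ge obs\} + 1)/(nsim + 1)$, which cannot be
zero. Traits are compared on their own (residual) scales by default; a
`standardize` flag divides by trait SDs first.

# The synthetic-data generator

`make_study_fixture()` emulates the joint structure the analysis assumes,
and its defaults are the package's reference conditions: 50 species on an
ultrametric pure-birth tree of depth 180 Myr (about the span of crown
mammal evolution); a driver log-volume evolving by BM (rate 0.003 per Myr,
giving realistic ~0.7 dex spread); a response log-volume with allometric
slope 1.3 (slopes above unity are the phenomenon of interest) and intercept
0.15 dex; residuals with phylogenetic signal $\lambda = 0.9$ and SD 0.15
dex, generated as $\sqrt\lambda \cdot \text{BM} + \sqrt{1-\lambda} \cdot
\text{white noise}$ — the standard generative reading of Pagel's lambda,
exact on an ultrametric tree; intercept grades of $+0.5$ and $-0.55$ dex
planted on two disjoint clades of ~8 species picked deterministically from
the tree (so grade identity survives re-simulation under the same seed); an
optional cognition trait linearly linked to the residuals (slope 1, noise
0.1) on a designated ~20-species subclade; a rest-of-brain volume 1.1 dex
above the driver with extra BM noise; and generation times uniform on 2–25
years. Simulation is exact node-to-node transition sampling for both BM and
OU (no Euler discretization), with the per-branch normal draws consumed in
identical order so the OU simulator converges pathwise to the BM simulator
as $\alpha \to 0$. Everything is bit-reproducible under a seed.

What the generator does *not* emulate: measurement error and intraspecific
variation, correlated residual structure between the two residual measures,
non-ultrametric sampling (fossils), diversification-linked trait change,
and body-size allometry of generation time. Passing tests on fixtures
therefore demonstrate statistical correctness of the machinery under its
own assumptions, not robustness to these real-data complications.

# Problem sizes, tolerances, and numerical choices

Worked examples and the acceptance script use 50-species fixtures with
rjMCMC chains of $2 \times 10^4$–$5 \times 10^4$ iterations (thinned by
20–25), which mix well at these data sizes; production analyses of
empirical datasets should use the long chains the method is usually run
with ($10^7$ iterations, thinned by 100 — the package default), set via the
`chain` entry of the pipeline config. Lambda optimization uses a 0.001 grid
step; the mvBM state iteration stops at $10^{-6}$ trait units; OU
covariances failing Cholesky return the likelihood sentinel; zero-length
branches are floored at $10^{-12}$ in the ancestral-state Laplacian;
generation-time ties break lexicographically; trees and traits are matched
by name intersection with a warning listing dropped names. Traits are not
z-scored before OU fitting (no standardization is applied anywhere unless
explicitly requested). The empirical dataset the pipeline was designed
around is not redistributable here: `study_dataset()` documents the
expected file layout and fails loudly until the published supplementary
files are supplied.

# A minimal run

```{r example, eval = FALSE}
fx <- make_study_fixture(fixture_spec(seed = 7))
config <- list(
  tree = fx$tree, traits = fx$traits, seed = 11,
  chain = list(iterations = 2e4, thin = 20),
  grades = list(groups = list(high = fx$truth$high_clade,
                              low = fx$truth$low_clade)),
  nsim = 999
)
run <- run_full_analysis(config)
run
```

# Known limitations

Single trait per OU analysis (no multivariate optima); one $\alpha$ and
$\sigma^2$ shared across regimes (shifts move optima only); no
measurement-error model; no information-criterion model selection between
BM/OU (the grade confirmation is the least-squares translation instead);
the variable-rates reversible-jump BM estimator is out of scope (mvBM is
the lineage-rate method here); convergence diagnostics are limited to the
internal likelihood re-check, acceptance-rate reporting, and seed-to-seed
comparison.
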