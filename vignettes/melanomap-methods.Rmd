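---
title: "Models and methods behind melanomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind melanomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

melanomap studies a rare, concealed binary trait — melanin-rich black skin
hidden under feathers — across a species-level phylogeny, and asks whether
its spatial distribution tracks ultraviolet exposure, the pattern known as
Gloger's rule. The package chains five statistical stages, each usable on
its own, and pairs every stage with a synthetic-data generator that knows
its own ground truth. This vignette explains the models, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic worlds do and do not establish about real data.

## The two-state Mk model

Trait evolution is modelled as a continuous-time Markov chain on states
$\{0,1\}$ with gain rate $q_{01}$ and loss rate $q_{10}$ per unit branch
length. With $s = q_{01} + q_{10}$ the transition probabilities have the
closed form

$$P(0 \to 1, t) = \frac{q_{01}}{s}\left(1 - e^{-st}\right),$$

and symmetrically for losses; `mk_transition_prob()` returns the exact
identity at $t = 0$. The likelihood of the tip data is computed by
Felsenstein's pruning algorithm (`mk_loglik()`) with per-node rescaling, so
trees with thousands of tips do not underflow. Two model classes are
fitted by `fit_mk()`: equal rates (ER, $q_{01} = q_{10}$) and all rates
different (ARD); they are compared by a likelihood-ratio test on one
degree of freedom (`lrt_er_vs_ard()`).

Numerical choices:

* rates are optimized on the log scale; ER uses Brent's method on a
  bracketing interval, ARD uses Nelder-Mead from at least five starts
  spanning $10^{-4}$ to $1$ expected transitions per unit tree depth, two
  asymmetric starts, and the ER optimum — the last guarantees
  $\ell_{ARD} \ge \ell_{ER}$ up to round-off;
* the root is weighted by a flat prior by default. The stationary and
  fixed-state treatments are available; analyses of rare traits are mildly
  sensitive to this choice, so reports carry the setting;
* zero-length branches (including those introduced when
  `resolve_polytomies()` expands multifurcations deterministically) use an
  exact identity transition matrix, which is why likelihoods and the D
  statistic are invariant to the resolution;
* a monomorphic trait yields a boundary-flagged fit, never a silent one.

`marginal_asr()` combines the postorder pass with a preorder pass to give
each node's posterior state probabilities; the two passes are checked in
the tests against brute-force enumeration over all internal-state
assignments, with transition probabilities from an independent matrix
exponential.

## Stochastic character mapping

`sample_histories()` draws complete trait histories conditional on the tip
data, with rates fixed at their maximum-likelihood estimates (empirical
Bayes; integrating over rate uncertainty is out of scope and would mainly
widen the origin-count distribution). Node states are drawn exactly from
their joint conditional distribution — the root from its marginal, each
child given its parent — and each branch is filled in by an
endpoint-conditioned bridge: rejection sampling of the forward process,
falling back after 100 rejections to a uniformization sampler that is
exact for any endpoint pair, so sampling cannot fail. Gains and losses are
the $0\to1$ and $1\to0$ segment boundaries; `summarize_maps()` reports
their distribution across maps (median and mean — the median is the
headline summary for "number of origins") and the per-edge posterior
occupancy of the derived state, the density map.

## Phylogenetic signal: the D statistic

`sister_diff_sum()` propagates tip values rootward by unweighted averaging
of the two daughter values and sums $|v_a - v_b|$ over internal nodes
(the unweighted variant matches the behaviour of the widely used reference
implementation; an inverse-branch-length-weighted variant is available
behind the `weighted` flag — it changes the null means but not the scaled
statistic's anchors, since observed sum and both nulls use the same
estimator). `d_statistic()` scales the
observed sum between two simulated nulls:

$$D = \frac{d_{obs} - \overline{d_b}}{\overline{d_r} - \overline{d_b}},$$

where $d_r$ comes from prevalence-preserving tip shuffles (random
expectation, $D = 1$) and $d_b$ from unit-rate Brownian liabilities
thresholded so the simulated prevalence equals the observed count exactly,
ties broken by rank (Brownian expectation, $D = 0$). Both nulls default to
1000 replicates (minimum 100 enforced). Tail conventions:
$p_{random} = \Pr(d_r \le d_{obs})$ and $p_{brownian} = \Pr(d_b \ge
d_{obs})$; a strongly over-dispersed trait can drive both towards zero
while $D$ approaches or exceeds 1, which is the regime reported for
repeatedly evolving traits.

## Phylogenetic logistic regression

The trait is regressed on standardized covariates through a latent
liability:

$$\mathrm{logit}\,\Pr(y_i = 1) = x_i^\top \beta + b_i,\qquad
b \sim N(0,\ \alpha C),$$

where $C$ is the tree's shared-path correlation matrix and $\alpha \ge 0$
measures the strength of tree-structured residual correlation. Estimation
maximizes a Firth-penalized joint objective (the penalty
$\tfrac12\log\det X^\top W X$ keeps estimates finite under complete
separation, which rare traits produce often) by damped Newton iterations
over $(\beta, b)$; $\alpha$ is chosen by maximizing the Laplace-
approximate marginal likelihood over a log-scale search, with the boundary
$\alpha = 0$ — ordinary (Firth) logistic regression — always evaluated as
a candidate. Standard errors come from the observed information with the
latent field profiled out.

Two deliberate design choices:

* this estimator is a latent-liability phylogenetic GLMM, not a
  re-implementation of the Ives–Garland evolving-trait model used by the
  original tooling. It shares the $\alpha = 0$ logistic limit and is
  checked at that limit against `glm()` to $10^{-3}$; empirical
  coefficients from the original tool are therefore comparable at the
  sign and significance level, not digit-for-digit;
* on a star phylogeny $C$ is the identity and binary data cannot
  distinguish an iid latent variance from the intercept scale, so
  $\alpha$ is fixed at 0 — which is also what "no shared history" means
  scientifically.

`r2_lik()` implements $R^2 = 1 - \exp(-\tfrac{2}{n}(\ell_{full} -
\ell_{null}))$, clamped to $[0, 1)$. Because the log-likelihoods are
Laplace approximations evaluated at penalized modes, a full model whose
extra covariates carry no information can sit slightly (up to a few
tenths) below the null; such deficits clamp to zero, and only larger ones
raise an error. Fit the null at the full model's $\alpha$ for a clean
nested comparison — `model_screen()` and the pipeline do this
automatically. `model_screen()` ranks covariate sets by AIC with
declaration-order tie-breaks, optionally within user-supplied clade
partitions (e.g. passerines versus non-passerines); it exposes all fits
rather than guessing which combination a summary range referred to.

Feather colour enters as one-hot indicators against a `brown` reference
level — the most common dull colour; the original analysis does not state
its reference, so coefficients for colour categories are interpretable
only relative to this choice.

## Maximum-entropy niche model

All black-skinned species are pooled into one pseudo-species: occurrences
are thinned per species (2-degree cells, at most 50 records per species,
stratified across occupied cells first, then within cells — so
`thin_occurrences()` is idempotent and a species with fewer records keeps
them all), then concatenated. The trait distribution over background
cells is the Gibbs model

$$p_\lambda(c) = \frac{\exp(f(c)^\top \lambda)}{\sum_{c'}
\exp(f(c')^\top \lambda)},$$

with linear and quadratic features of each environmental layer, min-max
scaled over the background. Restricting features to linear + quadratic
keeps the problem convex and the response curves interpretable; hinge and
product features of the reference tool are deliberately omitted. The
penalized negative log-likelihood (L1, per-feature weight
$reg \cdot s_j/\sqrt{m}$ with $s_j$ the presence-sample standard
deviation of the feature and $m$ the presence count — the reference
tool's scaling, without which a literal unit penalty on scaled features
zeroes every weight) is minimized by greedy coordinate descent with soft
thresholding and backtracking, stopping when the largest KKT violation
falls below $10^{-6}$. At `reg = 0` the fit solves the exact
moment-matching condition, verified in the tests against one-dimensional
root finding.

Each coordinate update is attributed to its variable, giving the
per-variable percentage contribution table; a seeded permutation
importance is reported alongside. Suitability is the cloglog transform
$1 - \exp(-e^{H} p_\lambda(c))$ with $H$ the entropy of the cell
distribution — monotone in the raw density, so rankings are
transform-free. `response_curve()` varies one variable over its observed
range with the others at background means; `difference_map()` subtracts a
max-normalized predictor from suitability (values near zero mean the
predictor alone explains the predicted trait surface), and
`relative_diversity()` normalizes a richness raster by its maximum.
Background is every valid cell — desk-scale grids need no background
subsample — with a seeded `bg_subsample` cap for large grids that always
retains the presence cells. Four variables (UV-B, minimum and maximum temperature,
precipitation) are the default set; any subset can be passed.

## Synthetic worlds: what they emulate, and what they do not

`synth_world()` mirrors the empirical regime: a birth–death tree
(forward Gillespie, conditioned on survival, pendant branches extended by
the next inter-event time so the pure-birth crown depth has expectation
$\sum_{k=2}^{n} 1/(bk)$) rescaled to depth 100; Mk rates 0.005/0.071 per
unit depth giving roughly 5% trait prevalence from a state-0 root;
covariates mixing Brownian and iid components with known logit effects
($\beta_{uv} = 1$, $\beta_{mass} = 0$, $\beta_{bald} = 0.8$); four
spatially autocorrelated rasters with the UV–maximum-temperature
correlation set to 0.7 (fields are empirically whitened before Cholesky
mixing, so sample correlations hit their targets exactly); and
occurrences drawn from an exponential UV-driven suitability surface,
optionally warped by a collector-bias raster that concentrates sampling
away from high-UV cells.

Passing the recovery tests on these worlds shows the estimators are
correct under their own generating assumptions. It does not show that
real museum scores are error-free, that the real phylogeny is known
without error, that real covariates act linearly on the logit scale, or
that real collector bias is a smooth multiplicative field — those remain
assumptions when the pipeline is pointed at empirical data. The
headline empirical numbers (150-ish head origins, a
loss/gain ratio near 15, $D > 0.98$) additionally require the real bird
phylogeny and trait table, which the package treats as optional external
inputs.

## Problem sizes and reproducibility

Every stochastic function takes a mandatory integer seed, and the
pipeline derives logged per-stage sub-seeds from one master seed; the same
configuration and seed produce byte-identical JSON reports. The test
suite exercises exhaustive oracles on trees of up to 5 tips, calibration
at 120–600 tips with 50–500 replicates, and niche-model recovery on
40×40-cell grids with up to 8000 occurrences; `scripts/acceptance.R`
re-runs the whole chain on an 800-tip world. These sizes were chosen so
the full verification runs on a laptop in minutes while keeping
Monte-Carlo error well inside each test's tolerance.
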