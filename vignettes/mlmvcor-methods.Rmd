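---
title: "Pooling correlation matrices with multilevel multivariate random-effects models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling correlation matrices with multilevel multivariate random-effects models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlmvcor)
```

## The problem

Meta-analyses of multi-variable instruments often collect one *correlation
matrix* per independent sample, and primary studies frequently contribute
several samples (sites, cohorts, countries). Two kinds of dependence then
coexist:

* **correlational multiplicity** — the `I(I-1)/2` correlations within one
  sample share variables and participants, so their sampling errors covary;
* **hierarchical multiplicity** — samples nested in the same study share
  study-level influences, so their true effects covary.

`mlmvcor` pools such data with a three-level multivariate random-effects
model. Writing `r_ijk` for the `i`-th correlation ("cell", an unordered
variable pair) in sample `j` of study `k`:

```
r_jk = beta + w_k + u_jk + e_jk
e_jk ~ N(0, V_jk)        (Level 1: sampling error, V_jk known)
u_jk ~ N(0, T)           (Level 2: within-study heterogeneity)
w_k  ~ N(0, Gamma)       (Level 3: between-study heterogeneity)
```

`beta` holds one pooled correlation per cell; `T` and `Gamma` hold per-cell
heterogeneity variances (`tau^2_i`, `gamma^2_i`) and, off the diagonal,
covariances formed from fixed correlations `rho` (within) and `phi`
(between). Rows missing from a sample's matrix are simply absent from the
likelihood — no imputation, no study exclusion.

## Level-1 covariance

`build_vmat()` constructs one symmetric block per sample from large-sample
theory for Pearson correlations: `var(r) = (1 - rho^2)^2 / n` on the
diagonal, and the Olkin–Siotani expressions for pairs of correlations that do
or do not share a variable off the diagonal. Each sample's own observed
correlations serve as plug-in values; a correlation a formula needs but the
sample did not report is substituted by the n-weighted mean of that cell
across samples (or zero), and every substitution is logged. Published
variants of these formulas differ in the denominator (`n` versus `n - 1`);
the `denominator` argument makes that choice explicit rather than silent.
Fisher-z analyses use `1/(n - 3)` variances with delta-method covariances.
Blocks that come out indefinite (possible with extreme observed values) are
repaired by eigenvalue clipping that preserves the diagonal, and repairs are
logged.

## Working models and selection

Four structures for `(T, Gamma)` span the practical range between
flexibility and parsimony:

| Model | Within `T` | Between `Gamma` | Variance parameters |
|---|---|---|---|
| 1 | HCS (per-cell `tau^2_i`) | HCS (per-cell `gamma^2_i`) | `2C` |
| 2 | HCS | CS (one `gamma^2`) | `C + 1` |
| 3 | CS (one `tau^2`) | HCS | `C + 1` |
| 4 | CS | CS | `2` |

HCS is heteroscedastic compound symmetry (per-cell variances, one shared
random-effect correlation); CS constrains the variances to be equal; DIAG
and ID are their zero-correlation special cases. `rho` and `phi` are fixed
inputs in `[0, 1]`, never estimated — data rarely identify them — and
`sensitivity_sweep()` exists precisely to show how conclusions move across
the conventional grid `{0, 0.5, 1}` and between the raw and Fisher-z scales.

Models 2–4 are nested in Model 1 (and 4 in 2 and 3), so REML
likelihood-ratio tests with equal fixed designs are valid alongside
information criteria. `run_decision_scheme()` makes the selection rule
explicit: take the minimum-BIC model, and escalate to a fuller model while
any admissible LRT rejects the current one at `alpha = 0.05`. All evidence
(IC table, every LRT) is returned so the rule can be overruled on
substantive grounds.

## Estimation

Variance parameters are optimized on the log scale (`log tau^2`,
`log gamma^2`), which enforces positivity without constrained optimizers; a
parameter driven to `exp(-30)` is reported at the boundary and flagged.
The restricted log-likelihood

```
-0.5 [ (N - p) log 2pi + log|M| + log|X' M^-1 X| + (y - X beta)' M^-1 (y - X beta) ]
```

is evaluated study-block by study-block — `M` is block-diagonal by study, so
the full `N x N` matrix is never materialized — with an analytic gradient
obtained from the rank structure of `dM/d log tau^2_i` (per-cell indicator
plus rank-one pieces). Optimization uses `nlminb` from four fixed starting
points (variances in `{1e-4, 1e-2}` crossed between levels, short probe runs,
then a full run from the best probe), so fits are deterministic: no random
number is drawn anywhere in estimation. A non-positive-definite `M` during a
step returns a penalty, never a crash. Convergence requires the optimizer's
own criterion or a numerically flat gradient on the interior coordinates
(boundary-pinned variances are excluded from that check).

Information criteria follow one fixed convention: under REML the parameter
count is the number of free variance components and the effective sample
size is `N - p`; under ML both fixed and variance parameters count and the
size is `N`. `AICc = AIC + 2q(q+1)/(m - q - 1)`, BIC uses `log m`.
Comparisons across software should therefore rely on IC *ordering*, not
levels; the package's likelihoods agree with independent implementations up
to the documented constant.

## Inference

`tidy()` gives normal-theory Wald tests and intervals from the model-based
covariance. `robust_vcov()` provides cluster-robust (sandwich) standard
errors with primary studies as clusters: CR0, CR1 (`G/(G-1)` inflation), and
the default CR2, which whitens each study block with the fitted marginal
covariance, applies the symmetric `(I - H)^{-1/2}` cluster adjustment, and
derives per-coefficient Satterthwaite degrees of freedom from the influence
decomposition — the small-sample standard when studies are few. The residual
heterogeneity statistic `Q` comes from the fixed-effects GLS fit weighted by
the full block-diagonal `V^{-1}` with `df = N - p`.

LRTs between fits with boundary-pinned variances report the naive chi-square
p-value and flag the caveat (the mixture null is not implemented), which
makes those tests conservative.

## Moderators

`fit_moderated()` crosses cells with a moderator. The interaction
parameterization keeps cell main effects as intercepts (reference-level
pooled correlations) plus per-cell moderator effects; the subgroup
parameterization estimates one pooled correlation per cell-by-level
combination and deliberately performs no between-group test (an explicit
`contrast_test()` covers that need). Continuous moderators enter
untransformed — scale is the analyst's declaration, never rescaled silently —
with an optional centering flag. Variance explained compares heterogeneity
estimates against the unmoderated fit per level and per cell,
`R^2 = max(0, (sigma2_null - sigma2_mod)/sigma2_null)`; negative raw values
are routine sampling fluctuation, so they are truncated at zero and flagged
rather than hidden.

## The synthetic-data generator

`simulate_cor_data()` draws the model's own generative process: per-study
and per-sample random effects over cells, latent correlation vectors clamped
to `(-0.999, 0.999)`, then either raw multivariate-normal data whose Pearson
correlations form the observations (`exact` mode) or draws from the
large-sample normal approximation at the latent values (`asymptotic` mode).
Latent matrices outside the set of valid correlation matrices are repaired
by eigenvalue clipping with diagonal renormalization; clamp and repair rates
are recorded, and a clamp rate above 5% raises a warning because the
requested heterogeneity then collides with the admissible range.

In asymptotic mode the Level-1 covariance can be evaluated at each sample's
latent correlations (`v_at = "latent"`, the default and the more realistic
emulation) or at the population values (`v_at = "population"`). The
distinction matters: with latent-value covariances, V co-varies with the
random effects, which violates the estimator's assumption that V is a known
exogenous constant — the model's own data-generating process corresponds to
`v_at = "population"`. Calibration checks (coverage, unbiasedness) therefore
run under the population-value setting, while the latent-value and exact
modes quantify how much the violation costs (see below).

Defaults mirror a typical item-correlation meta-analysis: 5 variables (10
cells), 62 studies, 1–4 samples per study with mean 1.4, lognormal sample
sizes with median near 327 clamped to `[99, 12706]`, population correlations
near 0.4, and heterogeneity variances of order `10^-3` (the scale of
published per-cell estimates, which ranged from near zero to about 0.009).
Parameter-recovery runs in the tests use 100 studies of 2 samples at
`n = 500` — sizes chosen so that several hundred REML fits complete in
minutes while keeping Monte-Carlo error small.

What the generator does *not* emulate: non-normal raw data, publication
bias, informative (MNAR) missingness, or measurement error. Passing tests
show the estimator recovers its own model; they cannot certify behaviour
under those violations.

## Known properties and limitations

* **Raw-scale weighting bias.** The sampling (co)variances of correlations
  depend on the correlations themselves (`(1 - r^2)^2 / n` on the diagonal),
  so when the generating covariances follow the latent values —
  `v_at = "latent"`, exact mode, or observed-value plug-ins — the GLS
  weights co-vary with the effects and raw-scale pooled estimates drift
  slightly upward (about `+0.006` at `tau^2 + gamma^2 = 0.015`, `n = 500` in
  our simulations, costing a few points of coverage). Under the strictly
  model-faithful `v_at = "population"` generation the same estimator is
  unbiased with nominal coverage, which localizes the effect in the
  endogeneity of `V`, not in the estimation. Remedies when it matters:
  the Fisher-z scale (`1/(n - 3)` variances, free of `r`) or the
  `plugin = "pooled"` covariance policy, which evaluates every formula
  input at the n-weighted pooled correlations so weights are common across
  samples.
* **Plug-in covariances.** `parameter_recovery(vmat = "true")` hands the
  fitter the generator's own Level-1 blocks (the known-V assumption), while
  `vmat = "plugin"` folds the analyst's observed-value plug-in error into
  the results.
* **Identification.** With no study contributing two or more samples, `tau^2`
  and `gamma^2` are identified only in sum; fits warn and the decision
  report propagates the warning.
* **Fixed `rho`, `phi`.** These are assumptions, not estimates; conclusions
  sensitive to the sweep grid should be reported as such.

## Numerical choices

Symmetry is enforced as `(B + B')/2` before any decomposition. PSD checks
use an eigenvalue floor of `-1e-10` before repair. Cell labels canonicalize
to "A–B" (en dash) with A before B in the declared variable roster, so
reversed input pairs are one cell. Ties in model selection resolve to the
smaller (more parsimonious) model id through the rank ordering. All
randomness flows from a single user-supplied seed; estimation itself is
RNG-free, so identical inputs reproduce identical outputs bit for bit.
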