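---
title: "Models and methods behind provtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind provtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provtrial)
```

provtrial analyzes replicated common-garden (provenance) trials of
open-pollinated tree families. This vignette is the package's account of the
statistical machinery: the models, the assumptions they lean on, the
numerical choices, and what the synthetic-data tests do and do not
demonstrate about real trials.

## The design and its assumptions

A trial plants offspring of known mother trees ("families") from several
seed origins ("provenances") in randomized blocks at several sites. The
default dimensions throughout the package mirror a 10-year pedunculate oak
trial: 3 sites x 3 blocks x 10 provenances x 22 families x 5 trees per
family per block = 9,900 trees, with heights in cm and dbh in cm.

Three assumptions carry the genetic interpretation:

1. **All offspring of a mother are half-sibs.** Open-pollinated progenies of
   wind-pollinated trees contain few full-sib pairs, and a modest full-sib
   fraction changes additive-variance estimates little. Under this
   assumption the additive relationship between two trees of the same mother
   is exactly 0.25, mothers are unrelated founders, and the relationship
   matrix A is block-diagonal by family. `sim_config(full_sib_fraction =)`
   exists to probe the assumption's cost.
2. **Mothers are not phenotyped.** They appear in the pedigree only to carry
   covariance. This makes the animal model exactly reparameterizable as a
   family model (family variance `s2_a/4`, residual `s2_e + 3/4 s2_a`),
   which the test suite exploits as an oracle and `estimate_qst()` exploits
   for fast bootstrap refits.
3. **Growth is a fitness surrogate.** The transfer function treats 10-year
   height/dbh as the response to climatic displacement; nothing in the
   machinery requires this reading, but the vertex interpretation does.

## The REML engine

All variance-component estimation runs through `reml_fit()`: Gaussian mixed
models with an arbitrary set of i.i.d. random factors plus at most one
pedigree-structured ("animal") term, fixed effects defaulting to an
intercept.

The implementation works on the mixed-model equations assembled sparsely
(Matrix/CHOLMOD). Writing `gamma_k = s2_k / s2_e`, the residual variance is
profiled out analytically and the restricted log-likelihood is evaluated
from one sparse Cholesky factorization per candidate `gamma`:
`log|H| + log|X'H^-1 X| = sum_k q_k log gamma_k + log|A| + log|C|`, with `C`
the coefficient matrix carrying `A^-1/gamma` blocks. The factor's symbolic
analysis is computed once and only the numeric slot is updated between
evaluations, so an evaluation costs a few milliseconds even with ~10,000
additive levels.

**Optimization.** The profiled criterion is maximized over `log gamma` by a
Nelder–Mead simplex followed by an L-BFGS-B polish, started from two points:
a sequential method-of-moments start (group-mean variances swept out from
the coarsest factor inward, so nested factors are not credited with their
parents' variance) and an equal-split start. Derivative-free search over the
profiled criterion is the same strategy lme4 uses for its deviance, and in
our testing it is markedly more robust on this model class than
score-driven average-information iterations, which need per-iteration traces
of inverse coefficient blocks (an O(n) sparse-solve burden at animal-model
sizes) and a monotonicity safeguard. Weakly identified corners — e.g. three
site levels crossed with eighteen nested blocks — can produce a saddle in
which a nested term absorbs its parent's variance while the parent pins to
zero; when a solution has a component at the bound, the search is restarted
once from that solution with the pinned components moved to the interior,
and the better optimum kept. On every model where both are defined, the
engine and lme4 agree in restricted log-likelihood and components to the
printed digits.

**Numerical choices.** Variance ratios are constrained to
`[1e-8, 1e8]` times the residual variance; an estimate at the lower bound is
reported as a boundary estimate with `NA` standard error, since the
asymptotic theory behind the SE does not hold there. Simplex convergence
uses a relative tolerance of 1e-8 with the quasi-Newton polish sharpening
the tail. Rows with missing response or grouping values are dropped before
fitting (mortality bookkeeping stays in the data; dead trees never enter
design matrices).

**Uncertainty.** Standard errors come from the inverse average-information
matrix evaluated exactly at the optimum via solves of the mixed-model
equations (no traces needed at a single point). Derived ratios —
heritability `h2 = s2_a/(s2_a + s2_e)` and, if requested, a
phenotypic-total variant — get delta-method intervals truncated to [0, 1].
The truncation can place a bound exactly at 0 or 1; an estimate is called
significant only when the lower bound exceeds 0. The printed heritability
formula deliberately excludes provenance and block variance from the
denominator; `estimate_h2(denominator = "phenotypic")` is the sensitivity
switch.

## Qst and its bootstrap

`Qst = s2_pop / (s2_pop + 2 s2_a)` assumes full outcrossing and additive
gene action; the multiplier 2 is kept exactly. The population term is the
provenance (or, via a mapping column, climatic-cluster) variance from the
same REML fit that provides `s2_a`. Because the trial has no neutral-marker
F_ST to compare against, the confidence interval is a family-level
nonparametric bootstrap: families are resampled with replacement within
populations, each resample refitted, and the percentile interval reported
(default 1,000 replicates; tests and the acceptance script use far fewer).
Resampled copies of a family are treated as new independent families, which
is the resampling unit appropriate to a half-sib design. Bootstrap refits
default to the family parameterization — exact for this pedigree shape —
because it is several-fold faster than re-assembling an animal model per
resample; `boot_model = "animal"` restores the literal model.

## GxE and ecovalence

`fit_gxe()` fits the full multi-site decomposition with *all* terms random
(site, provenance, family, block-in-site, provenance-by-site,
family-by-site, residual) and reports percentages of total variance — the
convention that makes "GxE explains 4% of variation"-style statements
well-defined. Treating site as random with three levels buys that
convention at the price of an imprecise site variance; its SE says so.

Ecovalence is computed from the **BLUPs** of the family-by-site term, not
raw cell means: shrinkage suppresses the sampling noise of 15-tree cells, so
ratios reflect structural instability. A family absent from a site receives
the BLUP of an unobserved level (0) with a message. An all-additive or
all-zero table has zero interaction sum of squares; ratios are then reported
as 0 with a degeneracy flag rather than dividing by zero. The 0.05 flagging
threshold is an arbitrary convention and is configurable.

One estimand subtlety worth stating: within any single site, family-by-site
deviations are indistinguishable from family effects, so within-site
"additive" variance absorbs them and within-site h2 drifts upward when GxE
variance is present. This is a property of the design, not of the
estimator; the package's recovery tests therefore use interaction-free
generative settings when a known h2 is required.

## The transfer model

`fit_transfer()` is ordinary least squares of individual-tree growth on the
climatic transfer distance `D = climate_prov - climate_site` and `D^2`,
fitted separately per site (sites differ too much in mean growth to pool),
with plain two-sided t-tests and no heteroscedasticity correction. Fitting
on individual trees reproduces the convention of large trial analyses
(large t values, small R^2); provenance means are used only for plotting.
Because all trees of a provenance share one `D`, provenance-level effects
act as correlated noise on 10 support points — the OLS standard errors are
conditional on that and the recovery test uses many synthetic provenances
with the provenance variance switched off to isolate the curvature. The
vertex `-b1/(2*b2)` is only reported for concave fits; a convex fit is
flagged as having no interior maximum.

## Functional traits

Trait formulas are implemented exactly as defined for this trial type:
SLA as **mass/area** in g/cm2 (the reciprocal of the common convention —
the output column is named `SLA_mass_per_area` to prevent silent misuse),
LDMC as dry/saturated mass, SHM as `MWMT/(MSP/1000)` (degC per m of
May–September precipitation; higher = drier). Theoretical hydraulic
conductivity uses the Hagen–Poiseuille form
`Kh = (pi rho_w / 128 eta) * VD * Dh^4` with water at 20 degC and the
hydraulic mean diameter `Dh = (sum D^4 / n)^(1/4)`, `D` the mean of minor
and major vessel axes. The fourth-root form is the dimensionally consistent
one; a literal `(sum D^4/n)/4` variant seen in print is available behind
`literal_dh = TRUE` for comparison only. The 95% vessel-area quantile uses
linear interpolation between order statistics (quantile type 7), stated
here because no convention is universal.

Provenance-level trait–climate regressions are simple linear models of
provenance means on SHM at seed origin, per site, with Benjamini–Hochberg
adjustment applied **within site across the trait family** — sites are
reported separately, so each site's trait set forms one test family;
other family definitions can be had by calling `bh_adjust()` directly.
Trait–growth associations are Pearson correlations at tree level or
provenance-mean level, per site and pooled.

## Climate clustering

Provenances are clustered on principal components of their standardized
climate variables (z-scores, since degC and mm mix). The screeplot "elbow"
is automated as the largest second difference of the within-cluster sum of
squares over k (k-means, 25 restarts, seeded); visual elbow choices do not
replicate, this rule does. k can be forced (e.g. to the published five
clusters). With only the four printed climate variables rather than the
thirteen used originally, the automated clustering need not reproduce the
published labels exactly; the shipped reference table therefore carries the
published cluster column as data.

## What the generator emulates — and what it does not

`simulate_garden()` draws every term of the multi-site model from its
stated normal law, builds breeding values explicitly (mother value /2 plus
Mendelian deviation of variance `3/4 s2_a`, giving half-sib covariance
`s2_a/4` by construction rather than by factorizing A), optionally bends
provenance-by-site means along `-c (MAT_prov - MAT_site)^2`, and applies
independent Bernoulli mortality. Default variance components sit at the
height scale of the shipped reference table (site 5000, provenance 2000,
block 60, additive 3600, provenance-by-site 620, family-by-site 280,
residual 11000 cm^2; survival 0.94; curvature 19 cm/degC^2). Provenance
climates default to the shipped ten-provenance table; site climates (and
provenance climates for other counts) are drawn uniformly over that table's
observed range, and May–September precipitation is synthesized as 45–55% of
MAP. The dbh trait is derived from the height phenotype with an added
noise term, i.e. with genetic correlation 1 — adequate for exercising
two-trait plumbing, not for multi-trait inference.

Not emulated: spatial autocorrelation within blocks, competition among
neighbours, longitudinal growth, selective mortality, measurement error
structure, and non-Gaussian traits. Passing recovery tests on this
generator therefore shows the estimators are correct under the stated
model; it cannot show robustness to field realities outside it.

## Problem sizes used in testing

The test suite and acceptance script size their simulations as the
package's own choice of desk-scale conditions: 50 seeded trial-shaped
replicates (9,900 trees each) for variance recovery; 50 interaction-free
replicates for h2 interval coverage (one site, n = 3,300 per fit) and
pooled Qst recovery at a generative Qst of 0.25; 1,000 null replicates for
the Benjamini–Hochberg error rate; Monte-Carlo checks of the half-sib
covariance at 10,000 families. Headline inferential values from the real
~9,900-tree oak dataset (e.g. site-level h2 around 0.4–0.5) depend on data
not shipped here and are not asserted anywhere in the package; recovery of
known synthetic truth is the testable claim.

## Known limitations

- Single-trait REML only; no spatial residuals; Gaussian responses only.
- The average-information covariance is asymptotic; intervals near the
  [0, 1] boundary rely on truncation rather than profile likelihood.
- The site variance in the all-random decomposition rests on three levels;
  its SE is honest but enormous, and percentages involving it inherit that
  uncertainty.
- Ecovalence flags are descriptive; no resampling-based significance is
  attached to them.
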