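---
title: "Estimating pollinator body size from the intertegular distance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pollinator body size from the intertegular distance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Dry weight (mg) is the standard operational measure of body size in bees and
hoverflies, but weighing dehydrated, pinned specimens is slow and
destructive. The intertegular distance (ITD, mm) — the span between the wing
bases across the thorax — is quick to measure and scales with mass by a
power law, `W = alpha * ITD^beta`, which is linear on ln–ln axes:

```
ln(W) = ln(alpha) + beta * ln(ITD)
```

`pollisize` embeds this law in a hierarchical Bayesian model so one fit can
serve specimens across sexes, taxonomic groups (bee families or hoverfly
subfamilies) and biogeographic regions:

```
ln(W_i) = X_i * gamma + u[region(i)] + v[species(i) in region(i)] + eps_i
u_r ~ Normal(0, sd_region^2)
v_s ~ Normal(0, sd_species^2)
eps_i ~ Normal(0, sigma^2)
```

The fixed part `X_i * gamma` always contains an intercept and (normally) the
`ln(ITD)` slope, optionally sex and group offsets and their interactions
with `ln(ITD)` (`model_spec()`). The random intercepts nest species within
region, so a species sampled in two regions carries a separate intercept in
each, and regional differences in the allometry are absorbed without making
the model region-specific.

The phylogenetic variant (`fit_interspecific_phylo()`) replaces the i.i.d.
species intercepts with a multivariate normal whose correlation comes from
a genus-backbone tree: `v ~ MVN(0, sd_species^2 * C)`, where `C` is the
shared-path-length matrix rescaled to unit diagonal. On a star tree with
equal tip lengths `C` is the identity and the two variants coincide — a
property the test suite checks numerically.

## Priors, sampling and convergence

Priors are weakly informative and overridable (`default_priors()`):
Normal(0, 5) on the ln-scale intercept, Normal(0, 2) on slopes and offsets,
half-Normal(0, 1) on all standard deviations. On the ln scale these are
broad relative to any plausible insect allometry — an exponent prior SD of
2 covers everything from strong negative allometry to twice the
mass–length exponent of isometry.

Models are sampled with JAGS (Gibbs sampling) for 2,000 iterations per
chain with a burn-in of 1,000 and 4 chains by default. Internally the
sampler uses a hierarchically centered, covariate-centered
reparameterization (species intercepts centered on their region's, regions
on the global intercept; design columns centered at their means). This is
an exact reparameterization — draws are transformed back before anything
user-facing sees them — chosen because the naive parameterization leaves
the intercept and the region-mean direction mixing very slowly.
Convergence is gated on split-R-hat over all sampled parameters at the
community threshold of 1.05; a failing fit is returned with a warning and
`converged = FALSE`, never silently. `mcmc_settings()` also accepts
`adapt_delta` and `max_tree_depth` for interoperability with Hamiltonian
samplers; they are recorded in the fit but have no Gibbs equivalent, and
the divergent-transition count is structurally zero for the same reason.

Two honest caveats, both visible in the package's own diagnostics rather
than hidden:

* On deeply structured phylogenies the global intercept of the
  phylogenetic variant is only weakly identified against the tree-wide
  mean of the species effects (the two trade off along a direction the
  likelihood barely constrains). The slope, sex and group terms, the
  variance components and all predictions are identified sums and mix
  well, but the intercept's R-hat can stay above the gate at default
  iteration counts, and such fits are flagged. This is a property of the
  PGLMM posterior, not of the sampler choice.
* At the synthetic defaults (40 species in 4 regions) the 90% credible
  interval for the ITD exponent is mildly anticonservative across repeated
  studies (frequentist coverage roughly 0.8): with four region clusters
  the exponent's between-cluster uncertainty is underestimated by any
  standard mixed-model machinery — an REML fit of the same studies shows
  the identical Wald-SE understatement. Prediction intervals, the quantity
  most users consume, are calibrated on target (see below).

## Prediction

`predict_dry_weight()` evaluates the linear predictor per posterior draw
and exponentiates per draw. The point estimate is the noise-free posterior
median on the mg scale, which is invariant under the exp transform, so no
smearing correction is needed. The SE and the 90% interval are posterior
*predictive*: each draw receives a residual `Normal(0, sigma)` perturbation
before exponentiation, so a nominal 90% interval is calibrated to contain
the measured dry weight of a fresh specimen about 90% of the time. The
interval-calibration check in the acceptance suite (1,000 fresh synthetic
specimens) lands at 0.90 empirical coverage; intervals built from the
linear predictor alone measure about 0.38 under the same conditions, which
is why the predictive convention was adopted.

Records of species unseen during fitting get their species effect
integrated over the posterior population distribution (a fresh
`Normal(0, sd_species)` draw per posterior draw); unseen regions likewise,
with a warning. This is deliberate: taxon-level models exist precisely to
serve species that were never weighed.

## Model selection

Models are ranked by species-grouped K-fold cross-validation (default
k = 10): the species list is permuted under a seed and dealt round-robin
into folds, so every specimen of a species shares a fold and held-out
species are entirely unseen by training. The score is
`-2 * sum(log posterior predictive density)` of held-out specimens
(deviance scale, lower is better) — a stated convention, since several
information-criterion-like scales exist. Held-out species' random effects
are marginalized analytically within each posterior draw; for phylogenetic
fits the held-out species effect is first conditioned on the training
species' effects through the tree covariance (a Gaussian conditional),
which is exactly how phylogenetic information can help predict an unseen
relative. Bayesian R-squared (per-draw explained-variance ratio, always in
[0, 1]) and RMSE on the mg scale complete the `compare_models()` table.

## Phylogenetic pipeline

* `prune_to_genera()` reduces a published genus backbone to the genera
  present in the data, preserving path lengths.
* `graft_species_polytomies()` attaches species to their genus as an
  equal-branch-length polytomy. The phrase "equal branch length relative to
  the genus branch length" admits several readings; the implemented rule
  splits the genus terminal edge at a configurable fraction (default 0.5):
  tips of length `f * e` below a stem of `(1 - f) * e`. This preserves
  every root-to-tip depth exactly (tested at 1e-9 relative tolerance) and
  gives congeners identical off-diagonal covariance, which is the formal
  counterpart of reading phylogenetic structure only at and above the
  genus level. Species whose genus is absent from the backbone are
  returned as an exclusion list, not an error.
* `chronogram_pl()` dates the tree by penalized likelihood with a
  correlated rate model (ape's implementation, root age fixed at 1, so
  depths are relative time). The smoothing default of 1 follows the
  common default for this method; the parameter is exposed. In practice
  the optimizer leaves a floor of rate variation (CV around 0.2) even at
  extreme smoothing, so the "single global rate" limit holds only
  approximately.
* `pagels_lambda()` is this package's own profiled maximum-likelihood
  implementation: for a candidate lambda the off-diagonal covariance is
  scaled, the ancestral mean and rate are profiled out analytically (GLS
  mean, ML variance), and the 1-D profile is maximized by Brent's method
  on [0, 1] — no gradients, no risk of leaving the admissible interval.
  It agrees with an independent implementation (phytools) to 1e-3 in the
  test suite. The LR test against lambda = 0 uses chi-squared(1) by
  default; because lambda = 0 lies on the boundary, a 50:50
  boundary-mixture p-value is available by flag. The function requires an
  ultrametric tree and refuses otherwise (on a non-ultrametric tree, tip
  depth differences confound the signal being measured).

## Intraspecific diagnostics and sample-size adequacy

Within one species and sex the package fits plain OLS on ln–ln axes
(`intraspecific_fit()`, minimum 4 specimens so the F test has df). These
fits are diagnostics: within-species allometry is typically weak and
environmentally confounded, and the package makes no attempt to dress it
up as prediction.

`adequacy_curve()` asks how many specimens are needed for a stable species
mean: for each subsample size n it draws `replicates` (default 100)
subsamples without replacement and records their means. The adequate
sample size is the smallest n from which the 2.5%–97.5% envelope of those
subsample means stays inside the t-based 95% confidence band of the
full-sample mean, for every larger n as well. The envelope — not the
replicate-averaged mean — is the right object to compare against the band:
subsample means are unbiased, so their average sits near the full-sample
mean at every n and would declare a single specimen adequate regardless of
noise. With lognormal traits at a realistic CV of about 0.3 and N = 60 the
rule lands in the tens of specimens, consistent with the 20–30 range
reported for real bee traits.

## The synthetic-data generator

`generator_truth()` / `generate_specimens()` emulate the structure of a
multi-region museum-specimen study: per-(group, sex) power-law
coefficients, lognormal species ITD medians (default median 2 mm, ln-SD
0.5) with per-specimen ln-scale jitter (0.1), region and
species-within-region random intercepts, and ln-scale residual noise.
Defaults — one group, 4 regions, 40 species with 5 specimens per sex,
exponent 2.6, male intercept offset -0.3, SDs 0.2 / 0.4 / 0.3 — sit inside
the range observed for real bees (intraspecific exponents roughly 1.2–2.8,
strong female-biased dimorphism) but are synthetic choices, not estimates.
Each draw stage (ITD, effects, jitter, noise) uses a named substream
derived from the seed, so extending the generator never perturbs existing
draws, and every generated table passes the package's own validation.

What the generator does *not* emulate: real species-abundance skew (every
species gets the same specimen count), measurement error by different
operators, pin-weight residual error, pollen loads, or correlation between
body size and sampling probability. Passing the recovery and calibration
suites therefore demonstrates internal correctness of the machinery on
well-specified data, not robustness to those field realities.

## Problem sizes used by the checks

The test and acceptance runs use reduced problem sizes chosen as the
smallest that leave the checked signal clearly above Monte-Carlo noise:
parameter recovery over 20 studies at the generator defaults with 2 chains
of 1,200 iterations (600 burn-in); CV-ranking consistency over 10
replicates of 16 species x 12 specimens with k = 4; interval calibration
on 1,000 fresh specimens; phylogenetic-signal recovery on 100-tip trees.
At these sizes the full suite completes in a few minutes on one CPU.

## Known limitations

* Only the ln-normal likelihood is provided; heteroscedastic or gamma
  alternatives are out of scope.
* Taxonomic labels are opaque strings: no synonymy resolution, no rank
  expansion (an equation scoped to "Apidae" does not match a query for
  "Apoidea").
* The packaged equation registry ships two transcribed published
  conversions (Cane's ITD–dry weight law; the Rogers–Hinds–Buschbom
  insect length–weight law) plus clearly labelled synthetic example
  equations for the remaining trait types; the synthetic entries exist so
  the registry code paths are exercisable out of the box and must be
  replaced with transcribed coefficients before scientific use.
* Pin-weight standard errors are recorded but not propagated into model
  uncertainty (they are one to three orders of magnitude below specimen
  weights).
* Infrageneric relationships are polytomies by construction; conclusions
  about phylogenetic signal are supported at and above the genus level
  only.
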