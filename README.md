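# pollisize

Estimate pollinator body size — dry weight in milligrams — from the
intertegular distance (ITD), the span in millimeters between the wing bases
across an insect's thorax. Dry weight drives foraging range, pollen load
and most other size-mediated pollination processes, but weighing dehydrated
pinned specimens is slow and destructive; the ITD takes seconds under a
stereo-microscope. `pollisize` is for pollination ecologists and trait-based
community ecologists who need defensible mass estimates (with uncertainty)
for bees and hoverflies, including species nobody has ever weighed.

At the core is the allometric power law `W = alpha * ITD^beta`, fitted on
ln–ln axes inside a Bayesian hierarchical model:

    ln(W) = ln(alpha) + beta * ln(ITD) + Sex + Group (+ interactions)
            + (1 | Region / Species)

with species nested within biogeographic region as random intercepts, and
an optional phylogenetically constrained variant in which the species
effects are multivariate normal with covariance proportional to the
shared-path-length matrix of a genus-backbone tree. Around the model the
package provides: specimen-table QC (pin-weight correction, introduced-range
exclusions), a registry of published power-law conversions (foraging
distance, tongue length, wing loading, nectar load), a phylogenetic
pipeline (polytomy grafting, penalized-likelihood chronograms, Pagel's
lambda), model selection by Bayesian R² and species-grouped K-fold CV,
per-species OLS diagnostics with a sample-size adequacy resampler, and a
synthetic-data generator with known truth.

## Worked example

Simulate a study with known truth (exponent 2.6, male offset −0.3,
region/species/residual SDs 0.2/0.4/0.3), fit the sex model, and predict
the weight of an unweighed species:

```r
library(pollisize)
sim <- generate_specimens(generator_truth(seed = 42))
fit <- fit_interspecific(sim$specimens, model_spec("sex"),
                         mcmc_settings(seed = 42))
summary(fit)
#>     parameter     median  ...    lo90    hi90   rhat
#> 1 (Intercept)  0.9072750       0.4855   1.3319  1.002
#> 2      ln_itd  2.6822311       2.5188   2.8255  1.019
#> 3     sexmale -0.2743800      -0.3222  -0.2249  1.000
#> 4       sigma  0.2969443       0.2793   0.3156  1.000
#> 5   sd_region  0.3834766       0.1585   0.9552  1.002
#> 6  sd_species  0.3365386       0.2732   0.4223  1.001
```

The ITD exponent's 90% interval (2.52–2.83) covers the generating value
2.6, the male offset recovers −0.3, and every split-R-hat is at the 1.0
that signals converged chains. Prediction integrates the species effect
over its population distribution for species the model never saw (note the
`new_species` flag and the widened interval):

```r
newbee <- data.frame(species = "Osmia nova", sex = "female",
                     region = "Europe", itd_mm = 2.8)
predict_dry_weight(fit, newbee)
#>   point_mg    se_mg     lo90     hi90       flags
#> 1 41.21611 22.60662 18.53689 89.88627 new_species
```

The point estimate is the posterior median on the mg scale; `lo90`/`hi90`
is a posterior-predictive interval calibrated to contain the measured dry
weight of a fresh specimen about 90% of the time. The same interface
evaluates registered literature equations — here the classic bee ITD–dry
weight law from the packaged registry:

```r
reg <- load_registry(system.file("extdata", "equation_registry.json",
                                 package = "pollisize"))
predict_dry_weight(reg[[1]], data.frame(itd_mm = 2.8))
#>   point_mg se_mg lo90 hi90      flags
#> 1 24.23057    NA   NA   NA point_only
```

A command-line wrapper (`exec/pollisize`) exposes the same workflows as
`simulate`, `fit`, `estimate`, `select` and `phylo` subcommands driven by a
YAML config; every run writes a manifest sufficient to reproduce it.

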