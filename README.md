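# HydroCongruence

Cross-community congruence analysis for multi-taxon wetland surveys
structured by a hydroperiod gradient.

## The problem

Prairie-pothole and similar depressional wetlands are organized by
hydroperiod — how long ponded water persists through the season. Birds,
aquatic macroinvertebrates and vascular plants all turn over along that
gradient, so their site-by-taxon matrices co-vary. The scientific
question is *why*: do communities merely respond in parallel to the
shared hydroperiod filter, or do they shape one another directly
(habitat and food provisioning, propagule dispersal)? And is the
strength of any cross-community relationship stationary between
wetlands that dry every summer and wetlands that stay ponded?

HydroCongruence is for community ecologists with two or more
site-matched abundance matrices and a small set of environmental
indicator variables who want those questions answered with a
permutation-tested, sample-size-aware workflow.

## The statistic

Abundance matrices are Hellinger-transformed
(`y_ij = sqrt(x_ij / Σ_k x_ik)`) and indicator matrices column
z-scored. Two row-matched matrices `X`, `Y` are compared by *symmetric
Procrustes superimposition*: both are column-centered, scaled to unit
total sum of squares, and optimally rotated (reflections allowed). With
`σ_i` the singular values of `XᵀY` after scaling,

    r  = Σ σ_i          (Procrustes correlation, pseudo-R, in [0, 1])
    m² = 1 − r²         (minimized residual sum of squares)

Significance is by PROTEST: rows of one matrix are permuted `B` times
and `p = (1 + #{r_perm ≥ r_obs}) / (B + 1)`. Around this core the
package provides

* a rarefaction sweep (`rarefactionCurve()`, `detectPlateau()`) that
  locates the sample size beyond which the congruence estimate
  stabilizes,
* a stratified balanced bootstrap (`balancedBootstrap()`,
  `congruenceTable()`) that equalizes unequal hydroperiod groups before
  comparing them,
* comparison logic (`percentElevation()`, `elevationSummary()`,
  `interpretPattern()`, `stationarityContrast()`) classifying the
  pattern as interactions-dominant or environment-consistent,
* a niche-based simulator (`syntheticScenario()`,
  `simulateWetlandDataset()`) generating gradient-structured
  communities with a tunable cross-community coupling `kappa`, and
* an end-to-end pipeline (`pipelineConfig()`, `runPipeline()`).

## Worked example

Simulate a 96-site wetland landscape whose bird community is strongly
coupled (`kappa = 0.9`) to the plant and invertebrate communities, then
run the full analysis:

```r
library(HydroCongruence)

cfg <- pipelineConfig(
    scenario  = scenarioInteractionsWorld(),          # kappa = 0.9
    rarefaction = list(nMin = 3, nMax = 30, B = 50),
    bootstrap   = list(iterations = 200, BPerm = 99),
    seed = 42)
report <- runPipeline(cfg)
report
#> Cross-community congruence report
#>   18 congruence records (3 groups x 6 pairs), target n = 39
#>   mean elevation = 39.9% (SE 2.5) -> interactions-dominant
#>   stationary pairs: 0 of 6

subset(as.data.frame(report$congruence), group == "all",
       select = c(pair, mean_r, ci_lo, ci_hi, median_p, significant))
#>                       pair mean_r ci_lo ci_hi median_p significant
#>        birds-invertebrates  0.840 0.819 0.857     0.01        TRUE
#>               birds-plants  0.862 0.844 0.877     0.01        TRUE
#>       invertebrates-plants  0.797 0.756 0.838     0.01        TRUE
#>          birds-hydroperiod  0.626 0.599 0.649     0.01        TRUE
#>  invertebrates-hydroperiod  0.587 0.563 0.613     0.01        TRUE
#>         plants-hydroperiod  0.575 0.535 0.613     0.01        TRUE
```

Reading the output: every pair is significantly congruent (median
PROTEST p = 0.01 at 99 permutations, below the 0.1 threshold), but the
three cross-community pairs (pseudo-R 0.80-0.86) sit well above the
three community-hydroperiod pairs (0.58-0.63). Per community that is a
36-44% elevation of cross-community over environmental congruence
(mean 39.9% ± SE 2.5), and since every cross-pair confidence interval
excludes the environmental values, the run is classified
interactions-dominant — the coupling built into the scenario is
recovered. The bootstrap compares all groups at the same size (here 39
sites, the long group's size) so the short/long contrast is not
confounded by sample size.

Real data enter through CSV files instead of a scenario:

```r
cfg <- pipelineConfig(
    communityPaths = c(birds = "birds.csv",
                       invertebrates = "inverts.csv",
                       plants = "plants.csv"),
    metadataPath = "metadata.csv",
    seed = 1)
```

with one site-by-taxon CSV per community (first column `site_id`) and a
metadata CSV with columns `site_id`, `permanence_class` (temporary,
seasonal, semi-permanent, permanent), `days_ponded`, `max_depth_cm`,
`amplitude_ratio`, `evap_index`. See `vignettes/congruence-methods.Rmd`
for the model, parameter meanings, and the package's caveats about
matrix dimensionality and stationarity verdicts.

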