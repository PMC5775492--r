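# halfsibqg

Quantitative genetics of nested half-sib common-garden experiments, with
egg size as the focal maternal-effect trait.

## The scientific problem

Early life history traits of fishes — hatch length, yolk sac volume,
growth to the free-feeding stage — are shaped by a mix of additive genetic
effects, maternal effects, and environment. In salmonids the dominant
maternal channel is per-offspring provisioning: the size of the egg. When
several populations are reared in a common garden (same water, same
temperatures), the among-population differences that remain are inherited,
and the question becomes *how much of that inheritance is egg size* —
both among populations (does egg size drive trait divergence?) and within
populations (does egg size explain the dam variance and the maternal
effect?).

The package implements the full analysis chain for a nested full-sib,
half-sib breeding design (each sire mated to two dams, each dam to one
sire; replicate egg containers per family per temperature treatment),
aimed at researchers analysing such experiments or simulating them for
power and design work.

## The models and statistics

Individual-level traits are modelled with Gaussian mixed models fit by
REML:

    z = mu + P + s + d + c + e                      (before egg size)
    z = mu + P + beta*EG + (P x EG) + s + d + c + e (after egg size)

where `P` is the population fixed effect, `EG` the dam's mean egg diameter
(a dam-level covariate), and `s ~ N(0, V_S)`, `d ~ N(0, V_D)`,
`c ~ N(0, V_C)`, `e ~ N(0, V_E)` are sire, dam-within-sire, container and
residual random effects. The interaction is dropped when a Type-II Wald
test finds it non-significant. Family-level derived traits (degree-day
growth rates, yolk conversion efficiency) use sire as the only random
term. From the variance components, with `V_P = V_S + V_D + V_C + V_E`:

- heritability `h^2 = 4 V_S / V_P` (a sire's variance captures a quarter
  of the additive variance in a half-sib design);
- maternal effect `m^2 = (V_D - V_S) / V_P`.

Uncertainty comes from a within-family bootstrap (offspring resampled
with replacement inside each family, preserving family sizes) with
bias-corrected accelerated (BCa) 95% intervals; variance components are
tested with a simulation-based restricted likelihood ratio test
(parametric bootstrap of the null fit). Among-population variance is
partitioned in the Nakagawa–Schielzeth fashion (fixed-effect contribution
variances over the observed rows), and phenotypic divergence is expressed
in haldanes,

    h = (mean2 - mean1) / (S_p * g),

pooled-SD-standardized change per generation, computed with and without
egg-size control via least-squares means. Multivariate population
differentiation uses z-scored traits, Euclidean distances, nMDS
(stress <= 0.15 acceptable), PERMANOVA (overall and pairwise), a
multivariate dispersion-homogeneity test, and Mantel correlation between
trait and egg-size distance matrices.

A synthetic-data generator (`simulate_chinook_study()` and the
lower-level `build_design()` / `simulate_offspring()`) reproduces the
statistical structure of a three-population, three-temperature Chinook
salmon hatchery experiment with known ground truth, so every stage of the
pipeline is testable against the parameters that generated the data.

## Worked example

```r
library(halfsibqg)

sim <- simulate_chinook_study(seed = 1)   # 68 families, 3 temperatures

spec_b <- model_spec("hatch_length_mm", temperature = 9.4)
spec_a <- model_spec("hatch_length_mm", temperature = 9.4, include_egg = TRUE)
boot_b <- family_bootstrap(sim$offspring, spec_b, n_iter = 500, seed = 2)
boot_a <- family_bootstrap(sim$offspring, spec_a, n_iter = 500, seed = 3)
ch <- compare_before_after(boot_b, boot_a)
ch[, c("parameter", "before", "after", "pct_reduction", "significant")]
#>   parameter before   after pct_reduction significant
#> 1       V_S  0.042  0.0802     -9.13e+01        TRUE
#> 2       V_D  0.257  0.0379      8.52e+01        TRUE
#> 3       V_C  0.000  0.0000            NA       FALSE
#> 4       V_E  0.519  0.5185      8.15e-04       FALSE
#> 5        h2  0.205  0.5042     -1.45e+02        TRUE
#> 6        m2  0.263 -0.0666      1.25e+02        TRUE
```

Adding the egg-size covariate removes 85% of the dam variance for hatch
length at 9.4 °C (0.257 → 0.038, non-overlapping BCa intervals): in these
synthetic data, as in the real system they emulate, egg size *is* most of
the maternal effect, while the residual variance is untouched. The
divergence rate of egg diameter itself, from the per-population summaries
(means 7.9 vs 6.6 mm, SEs 0.10 and 0.09, 20 and 26 females, g = 10
generations):

```r
haldane_rate(mean1 = 6.6, mean2 = 7.9, sd1 = 0.09 * sqrt(26),
             sd2 = 0.10 * sqrt(20), n1 = 26, n2 = 20, g = 10)
#> [1] 0.2864084
```

`run_pipeline(pipeline_config(...))` chains every stage — trait
derivation, before/after variance-component models, partitioning,
divergence rates, and the multivariate tests — deterministically under a
single seed, writing JSON/CSV reports.

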