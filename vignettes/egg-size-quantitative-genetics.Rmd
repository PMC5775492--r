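---
title: "Egg size, maternal effects and divergence in half-sib common-garden designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Egg size, maternal effects and divergence in half-sib common-garden designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halfsibqg)
```

# The design and the model

A nested full-sib, half-sib breeding design mates each sire to two dams and
each dam to a single sire. Offspring of the same dam are full sibs; offspring
of the same sire but different dams are half sibs. Because a sire contributes
only gametes, the among-sire variance `V_S` estimates a quarter of the
additive genetic variance, while the among-dam variance `V_D` contains the
same additive quarter *plus* everything a mother adds beyond her genes —
in fishes, chiefly per-offspring provisioning. That asymmetry is what lets
the design separate heritability,

$$h^2 = \frac{4\,V_S}{V_S + V_D + V_C + V_E},$$

from the maternal effect,

$$m^2 = \frac{V_D - V_S}{V_S + V_D + V_C + V_E}.$$

Individual-level traits are modelled as

$$z_{ijklm} = \mu + P_i + \beta\,\mathrm{EG}_{ik} + (P\times\mathrm{EG})
  + s_{ij} + d_{ijk} + c_{ijkl} + e_{ijklm},$$

with independent Gaussian random intercepts for sire, dam-within-sire and —
for hatch-stage traits measured in replicate containers — container. The
egg-size terms are present only in the "after" models; comparing fits before
and after the covariate attributes dam variance and among-population variance
to egg size. All models are fit by REML through `lme4`, which constrains
variances to be non-negative; boundary estimates of exactly zero are reported
as such. Family-level derived traits (growth rates, conversion efficiency)
collapse to one value per dam, so dam and container variance are inestimable
and sire is the only random term.

Assumptions worth keeping in mind: random effects are Gaussian and mutually
independent (no dominance, no sire-by-dam interaction, no common-environment
correlation beyond the container term), egg diameter is measured without
error and constant within a dam, and the populations share residual
variance within a temperature.

# Derived traits

From the raw stage measurements the package computes yolk sac volume as a
spheroid, $V = (\pi/6)\,L\,H^2$ (mm³, from yolk length `L` and height `H`),
yolk conversion efficiency $Y = (L_S - L_H)/V$ (mm/mm³ — length gained from
hatch to swim-up per unit yolk), and growth rates $G = (L_2 - L_1)/\Delta D$
on the growing-degree-day scale, the cumulative sum of mean daily
temperature. Two conventions are ours to fix because no standard exists:

* **Degree-day windows are half-open** (`[start, end)` on calendar days).
  This makes accumulation exactly additive —
  `dd(a,b) + dd(b,c) = dd(a,c)` — which an inclusive convention cannot do.
* **Family-level growth traits use family mean lengths** at each stage, with
  the family's own degree-day interval when the data carry one (a
  treatment-wide interval is the fallback). The mean is the natural
  aggregation for a destructive sampling scheme where different individuals
  are measured at each stage.

Negative conversion efficiencies (swim-up fish shorter than hatch fish) are
possible in small families; they are returned as-is with a warning rather
than censored, so that family-level models see an unbiased trait.

# Estimation and inference choices

**Egg-size centering.** The covariate enters grand-mean-centered within the
modelled data. Centering changes only the intercept, keeps population
effects interpretable as deviations at the average egg size, and makes
before/after intercepts comparable.

**Interaction screen.** The population-by-egg interaction is fit first and
dropped when its Type-II Wald p-value exceeds 0.05. Traits that keep the
interaction are excluded from the variance partition and from
egg-controlled divergence rates: with population-specific slopes there is no
single egg effect to separate from the population effect.

**Variance partition.** The fixed-effect variance of a model is the
variance, over the observed rows, of the combined fixed predictor
$X\hat\beta$; total variance is that plus the random-effect variances and
the residual. The population and egg shares are additionally reported from
their separate contribution variances (each effect's design columns times
its estimates). When populations differ in egg size the two contributions
are collinear, and the separate shares exceed the combined fixed share by
twice their covariance — reported explicitly as `fixed_covariance` rather
than silently folded into either share. Using the combined predictor for
the total is what makes the full-model fraction invariant when the egg
covariate merely reassigns variance from the dam term to the fixed part;
with the naive per-effect sum that invariance fails whenever the covariance
is non-negligible.

**Variance-component tests.** Significance of `V_S` and `V_D` uses a
restricted likelihood ratio test with a simulated null: the model without
the term is refit, `nsim` response vectors are drawn from that null fit
(parametric bootstrap on the same design), both models are refit to each,
and the p-value is the plus-one-corrected proportion of simulated statistics
at least as large as the observed one. The observed statistic is recomputed
through the identical refit pathway as the simulated ones, so optimizer
idiosyncrasies cancel between numerator and denominator of the comparison.
The statistic is location- and scale-invariant, which makes the parametric
bootstrap exact for its size up to Monte Carlo error. Null refits that fail
are dropped and counted; more than 5% failures aborts with diagnostics.

**Bootstrap.** Confidence intervals resample offspring within each family
with replacement, preserving every family's size exactly. This keeps the
design (and the dam-level covariates, which are constants of the dam) fixed
and targets within-family variation, preventing the overestimation of
genetic effects that family-level resampling produces. Intervals are BCa:
bias correction $z_0$ from the proportion of replicates below the point
estimate (ties counted half, so a symmetric bootstrap distribution yields
exactly $z_0 = 0$), acceleration from the delete-one-*family* jackknife —
the family is the independent sampling unit, so it is also the jackknife
unit. Adjusted percentile levels are clipped to $[1/(B+1),\,B/(B+1)]$.
Replicates with failed refits are dropped, not retried (retrying would bias
toward easily-fit configurations), and counted in the result. The package
default is 1000 replicates, a reasonable floor for stable BCa tails; raise
it for publication-grade intervals. Significance of a before/after change
is non-overlap of the two 95% intervals — conservative, but symmetric and
assumption-free.

**Degenerate inputs.** A degenerate bootstrap distribution collapses the
interval to the point with a warning; `V_P = 0` is a domain error for
`h^2`/`m^2`; negative `m^2` estimates are reported with a warning rather
than clipped, since clipping would bias the bootstrap distribution.

**Optimizer settings.** `lmer` runs with `nloptwrap` at tightened
tolerances (`xtol_abs = ftol_abs = 1e-10`). At the defaults, REML estimates
on balanced designs differ from the closed-form ANOVA estimators by ~1e-3
relative; at the tightened tolerances the agreement is ~1e-5, which the
oracle-equivalence tests rely on. Derivative checks are skipped
(`calc.derivs = FALSE`) for speed; convergence failures are promoted to
errors.

# Divergence rates

Haldanes standardize a mean difference by the pooled phenotypic SD
($(n-1)$-weighted two-sample formula) and the number of generations
separated (`g = 10` by default, matching roughly thirty years at a
three-year generation time; configurable). Egg-controlled rates replace the
raw means with least-squares means from the sire-random model with the egg
covariate, but keep the *raw* pooled SD in the denominator: the point of
the before/after comparison is to move only the numerator, so both rates
stay on one scale. Traits with no egg relationship (Wald p > 0.05) or with
a population-by-egg interaction are excluded from the controlled rates and
flagged. Pair-level summaries average over traits within a temperature with
a normal-theory t interval across traits — the simplest construction
consistent with treating traits as the replication unit.

# Multivariate differentiation

Family-by-temperature rows (the level at which all traits coexist) are
z-scored per trait and converted to Euclidean distances. nMDS minimizes
Kruskal stress-1 from multiple random starts (via `vegan::metaMDS` with
autotransformation off — these are not community data); stress is on the
0–1 scale and ordinations above 0.15 are flagged, not rejected. PERMANOVA
is implemented directly from its sums-of-squared-distances definition, with
free label permutation (the design is single-factor) and the plus-one
p-value correction; tiny instances can enumerate all permutations
exhaustively, which the test suite exploits as a brute-force oracle. The
dispersion-homogeneity check (the multivariate Levene analogue that
PERMANOVA assumes) uses distances to group centroids in a
principal-coordinate embedding via `vegan::betadisper`. The Mantel test
correlates lower triangles and permutes one matrix's rows and columns
simultaneously, one-sided for positive association.

# The synthetic-data generator

`simulate_chinook_study()` emulates a three-population Chinook salmon
common-garden experiment: 10/13/11 sires (hence 20/26/22 families) in the
Credit, Pine and Sydenham river populations, two dams per sire, two
40-egg containers per family in each of the 6.5, 9.4 and 15.2 °C
treatments. Dam egg diameters average 7.9/6.6/6.8 mm with marginal SDs near
0.45 mm, partly mediated by a positive female fork-length relationship
(slope 0.004 mm egg per mm fork length around population means of
860/780/800 mm); offspring traits follow the linear model above with
variance magnitudes of the order seen in salmonid early life history
(dam variance dominating hatch-stage traits, sire variance peaking at the
mid temperature). Survival is i.i.d. Bernoulli thinning per offspring
(0.9 at the cooler treatments, 0.6 at 15.2 °C), producing realistic
unbalanced family sizes, and juvenile measurements are absent at 15.2 °C,
mirroring a warm-treatment die-off. Crucially, the generator separates the
dam variance into an egg-mediated part ($\beta^2\,\mathrm{var(EG)}$) and an
independent residual `V_D_resid`, which is what makes the before/after
attribution analytically checkable: the "before" dam variance should
converge to $V_{D,\mathrm{resid}} + \beta^2\sigma^2_{EG}$ and the "after"
dam variance to $V_{D,\mathrm{resid}}$.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: non-Gaussian trait distributions,
temperature-dependent or size-selective mortality, within-dam egg-size
variation, cross-trait residual correlation, dominance or sire-by-dam
interaction variance, and measurement error in egg diameter. A single seed
governs all draws in a fixed documented order (pedigree first; then per
temperature: family degree-day jitter, survival, per-trait effects), so
identical configurations give byte-identical tables.

# Problem sizes used in the test suite

The property-based checks run at sizes chosen to balance Monte Carlo
resolution against a single-CPU run: parameter recovery uses 200 replicates
of 50 sires × 2 dams × 30 offspring; the egg-attribution checks 50
replicates of 20 sires × 2 dams × 20 offspring; calibration of the RLRT,
PERMANOVA and Mantel nulls 500 outer replicates with reduced inner
simulation counts (39–99), exploiting the fact that the plus-one-corrected
rejection rule has exactly nominal size for any inner count; BCa coverage
500 simulations of a Normal(0, 1) mean at n = 20 with 2000 bootstrap
replicates. Acceptance bands on the calibration checks are central 99%
binomial intervals at the nominal rate.

# Known limitations

Sire-dam decomposition only — no animal-model BLUP, no pedigree depth
beyond one generation, no dominance or epistasis partitions. The Wald tests
are asymptotic and mildly anti-conservative when the effective replication
(dams) is small; the interaction screen inherits that, which is one reason
excluded traits are flagged rather than silently omitted. Divergence-rate
intervals treat traits as independent replicates, ignoring their
correlation. Permutation tests permute freely and are not exact under
group-specific dispersion (the dispersion test is provided precisely to
check that assumption).
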