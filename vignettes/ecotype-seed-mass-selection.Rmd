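---
title: "Ecotype divergence and selection on seed mass: models and methods"
author: "ecosel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecotype divergence and selection on seed mass: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ecosel implements the statistical machinery of a local-adaptation study in a
perennial bunchgrass with two divergent ecotypes — a large-seeded upland
ecotype from xeric habitat, a small-seeded lowland ecotype from mesic
habitat, and an admixed sympatric group — plus a synthetic-data generator
that mirrors the two experimental designs: a greenhouse diversity panel
(123 genotypes from 7 population clusters, 3 replicate blocks) and a
reciprocal seed-addition field experiment (21 genotypes x 7 replicate plots
x 2 sites, 100 seeds per plot). This vignette explains each model, its
assumptions, the tunable parameters, and the numerical and design choices
made where conventions were open.

## The synthetic diversity panel

`simulate_panel()` draws every trait hierarchically on a model scale,

> value = ecotype mean + cluster effect + genotype effect + block residual,

with Gaussian effects at each level, then transforms to the data scale.
Sizes, masses and counts are generated on the log scale (positivity,
multiplicative biology), times on the raw scale, and germination percentage
on the logit scale. Seed mass is the anchor trait: it is a genotype-level
quantity (mass of 100 seeds divided by 100, in mg) with only a small
weighing residual across blocks, and the validator enforces near-constancy
(relative SD within genotype below 5%) rather than exact constancy.

The other seven traits are tied to seed mass through configurable
standardized-major-axis (SMA) links: within each ecotype the trait's
genetic deviation is `r * |b|` times the genetic deviation of log seed mass
plus independent noise, which makes the within-ecotype SMA slope of the
trait on log seed mass equal `b` with correlation `r`. Defaults encode the
qualitative patterns the field knows for this system — germination slows
and germination percentage falls with seed mass in the upland and sympatric
groups, root growth increases with seed mass everywhere, the seed
size–number trade-off is negative in uplands — with magnitudes chosen once
to give realistic overlap among ecotypes (classification accuracy in the
80–95% range rather than a clean separation). No published per-ecotype
trait means exist for this design, so these defaults are qualitative and
documented as such.

Mean annual temperature (MAT) of origin is constructed so that genotype
seed mass regresses on standardized MAT with the configured coefficient
(default −0.28 mg per SD, i.e. lighter seeds from warmer, mesic coastal
origins). The residual MAT variation is drawn hierarchically with
ecotype/cluster/genotype shares proportional to seed mass's own variance
decomposition, so the regression holds within clusters as well as
marginally; a nested mixed model then recovers the coefficient regardless
of how much it pools. The remaining climate covariates (elevation,
latitude, longitude, seasonalities, precipitation) are correlated with MAT
at realistic strengths but carry no independent effect on seed mass.

`trait_spec(empirical = TRUE)` switches a trait to *empirical* draws: each
stratum's effects are centered within their parent group and rescaled so
the stratum's mean square equals its balanced-ANOVA expectation. Realized
variance components then equal the configuration exactly, which is what a
single-realization parameter-recovery test needs; the price is that
effects are no longer strictly i.i.d. Gaussian, so empirical mode is for
recovery studies, not for emulating data.

What the generator does **not** emulate: maternal effects, seed dormancy
and seed-bank dynamics, spatial autocorrelation among field plots, weather,
and genotype-by-block interaction. Passing recovery tests therefore show
that the estimators are correct under the stated model, not that the model
captures every feature of real field data.

## The synthetic field experiment

`simulate_field()` draws, per plot, a correlated pair of plot effects
`(u_S, u_A)` from a bivariate normal (SDs 0.3, correlation 0.5 by default),
then

> seedlings ~ Poisson(exp(alpha_S + beta[site] z + v_S + u_S)), truncated at seeds added,
> adults ~ Poisson(exp(alpha_A + gamma_seedling S + gamma[site] z + v_A + u_A)), truncated at the seedling count,

where `z` is seed mass standardized across the experimental genotypes and
`v` are genotype effects. The truncation keeps synthetic counts physically
consistent (you cannot recruit more seedlings than seeds, nor more adults
than seedlings); the fitted model is untruncated, so recovery studies use
regimes where truncation rarely binds (expected counts well below 100 per
plot). Default seedling gradients are +0.20 per SD at the xeric site and
−0.56 at the mesic site — selection favouring large seeds in xeric and
small seeds in mesic habitat. The default mesic *adult* gradient is −1.5
rather than the much stronger point estimate a field study can produce
when large-seeded genotypes fail completely at a mesic site: on a
log-linear generator a gradient of −6 or more makes the truncation bound
the dominant regime (adult counts saturate at the seedling count for most
small-seeded plots), which no census shows; stronger regimes remain one
`field_config()` argument away. Control plots (7 per site) receive no seed
and emit zero counts — the generator has no seed-bank process.

## Ecotype discrimination (canonical discriminant analysis)

`lda_fit()` solves the generalized eigenproblem of between-group versus
pooled within-group scatter on genotype means. Traits are standardized to
unit pooled within-group variance before the eigensolve (numerical
stability; results are invariant to affine rescaling of any trait) and
axes are scaled to unit pooled within-group score variance. The eigenvalue
share of axis 1 is the "percent discrimination". Loadings are reported as
pooled within-group correlations between traits and canonical scores
(structure coefficients) — the convention under which "the trait with the
highest loading" is meaningful — with raw coefficients also available.
Classification uses equal priors and the pooled covariance;
*resubstitution* accuracy is the headline number (the convention of the
point-and-click software this analysis is usually run in), with
leave-one-out available via `lda_classify(method = "loo")`. Singular
within-group scatter aborts with advice to drop collinear traits or set a
ridge.

## Nested variance partition

`fit_nested_ranef()` fits the intercept-only Gaussian mixed model with
nested random intercepts for ecotype, population cluster within ecotype
and genotype within cluster, by REML via `lme4::lmer`. Because the lowland
ecotype contributes few genotypes, its three clusters are collapsed into
one group before fitting (an explicit, logged relabelling used only in
this stage). Replicate blocks identify the residual. Variances at the
boundary are reported as exact zeros. The optimizer is bobyqa with a tight
end trust-region radius (1e-12) so that on balanced designs the REML
solution matches the closed-form ANOVA estimators to ~1e-7. Proportions
divide each variance by the four-component total, residual included.

`bootstrap_proportions()` is a nonparametric case bootstrap whose
resampling unit is the *genotype within its population cluster* (clusters
and ecotypes fixed): resampled genotypes keep all their replicate rows
under a fresh label. Genotype-level resampling matches the inference
target (genotypes are the sampled units; blocks are not exchangeable
across genotypes); plain row resampling is available via a flag.
Replicates that fail to converge are dropped and counted, with a warning
(error under `strict = TRUE`) beyond 20%. Intervals are percentile
2.5/97.5. With only three ecotype levels the ecotype proportion is weakly
identified and its bootstrap interval is honest about that (it often
reaches zero).

## Climate-of-origin model averaging

`fit_global_lmm()` regresses genotype seed mass (mg) on seven
z-standardized climate/geography predictors with random intercepts for
ecotype and cluster-within-ecotype, fit by **ML** (not REML) so that AICc
is comparable across fixed-effect subsets. The response is one row per
genotype, which makes a genotype-level random intercept unidentifiable
against the residual; the parameter count is therefore intercept +
predictors + 2 random variances + residual (a constant offset in `k`
across candidates, so deltas and weights are unaffected by the
convention). The AICc sample size is the number of genotypes.
`all_subsets()` fits all 2^7 = 128 additive models on the identical row
set; `model_average()` retains the set with delta below 7 and performs
**full (zero-substituted) averaging**: absent coefficients enter as zeros,
the unconditional SE is `sum_i w_i sqrt(se_i^2 + (b_i - b_bar)^2)`, and
relative importance is the summed weight of retaining models; conditional
averages are available via a flag. `marginal_r2()` is the fixed-effect
variance share of the global ML fit.

## Ecotype-specific allometry (SMA)

`sma_fit()` implements the closed forms: slope `sign(r) s_y/s_x`,
intercept through the bivariate mean, association tested as `H0: r = 0` on
`n − 2` df, and the slope interval from
`B = F(0.95; 1, n−2)(1 − r^2)/(n − 2)`. Traits are analysed on the raw
scale by default (the study's plots are in raw units); a log-log option
exists since allometry is classically log-scale. `common_slope_test()`
profiles the likelihood-ratio objective
`−sum_i (n_i − 2) log(1 − r_uv,i(beta)^2)` over the candidate common slope
`beta`, where `u = y − beta x` and `v = y + beta x` are exactly
uncorrelated at a group's own SMA slope; the minimum is chi-squared with
`groups − 1` df under a common slope. The minimizer is located by a coarse
sign-aware log-spaced scan (400 points) refined by golden-section
optimization, and the implementation is verified against a brute-force
grid with step 1e-4. One structural property deserves emphasis: `r_uv^2`
depends on `beta` only through `beta^2`, so the test is *blind to the sign
of the slope* — groups whose slopes differ only in sign are not separated
by it, and the reported common slope takes the df-weighted majority sign
of the groups. Sign heterogeneity shows up instead in the per-group
correlation tests. Groups with fewer than three genotypes are skipped with
a warning and the degrees of freedom shrink accordingly; pairwise
comparisons reuse the statistic with Bonferroni correction.

## Recruitment GLMs

`fit_poisson_glm()` is a log-link Poisson GLM of seedling or adult counts
on ecotype, site and their interaction (control plots excluded; xeric and
lowland are the reference levels, configurable). No offset is used since
every treatment plot received 100 seeds; an offset option exists for
unequal designs. Term tests are **likelihood-ratio** chi-squares (the
interaction dropped from the full model, each main effect from the
main-effects model); Wald-style summaries can be derived from the
coefficient covariance if wanted. `pearson_gof()` reports
`X^2 = sum (obs − fit)^2/fit`, its df and the dispersion ratio; on default
synthetic data the dispersion exceeds 1 because genotype-level seed-mass
gradients and plot effects generate real extra-Poisson variation that a
six-cell ecotype-by-site model cannot absorb — the hierarchical model of
the next section is the remedy. `site_contrasts()` reports per-ecotype
cell means (`exp` of the linear predictor), delta-method SEs, the percent
difference defined as (favoured − other)/other x 100 with its direction,
and the Wald test of the within-ecotype site difference on the log scale.

## The joint hierarchical selection model

The centre of the package is the two-response hierarchical Bayesian model:
both counts are Poisson with a log link; seedlings are predicted by
standardized seed mass, site and their interaction; adults by the seedling
count (scaled by its sample SD), seed mass, site and the two two-way
interactions (seedling x site and seed mass x site; a three-way term is a
config switch — the reported per-site adult gradients are conditional on
seedling number, which the two-way structure provides). Each response has
a genotype random intercept, uncorrelated between responses, and the two
plot effects are correlated bivariate normal — the device that absorbs the
dependence of adults on seedlings within a plot. Priors are weakly
informative: Normal(0, sd 25) slopes, Normal(0, sd 10) intercepts,
half-Student-t(3, 0, 10) random-effect SDs, uniform(−1, 1) correlation.
The "sd 25" reading of the prior notation follows the convention of the
modelling software this class of model is usually fit in, and prior-only
sampling (`likelihood = FALSE`) verifies it: the slope posterior SD is 25.

`log_posterior()` is the complete joint density in plain R — Poisson
likelihoods, bivariate-normal plot effects, Gaussian genotype effects,
priors — and is the contract any sampler must target; the tests pin it
against an elementary loop-written oracle to 1e-8 and check that with
random effects pinned at zero and flat priors its mode reproduces the
Poisson GLM MLE.

`sample_posterior()` renders the model to JAGS and samples by Gibbs/slice
updates, three chains of 4000 iterations with the first half discarded by
default. Three implementation choices matter for mixing and are invisible
in the results: the design matrices are column-centered inside the sampler
(the intercept prior applies on the centered scale, as the reference
software does, and the reported intercept is back-transformed
deterministically); the plot and genotype effects use a non-centered
parameterization (`u = sd * e`, `e ~ N(0,1)`, with the correlated pair
built from its Cholesky), which lets the SDs and correlation move without
the latent field re-equilibrating; and fixed effects are initialized at
Poisson-GLM estimates. Determinism is exact given the seed (per-chain RNG
streams derived from it). Split-chain Rhat and effective sample sizes are
computed for all fixed effects and hyperparameters; any Rhat above 1.05
flags the run as unconverged (returned, with a warning). A Gibbs sampler
buys its simplicity with efficiency: on the default 294-plot design the
slowest movers (the seedling-covariate coefficient, the plot-effect
correlation and the adult plot-effect SD) need several-fold the nominal
chain length to reach the effective sample sizes a gradient-based sampler
would give at 3 x 4000; the diagnostics test runs 3 x 30000 with 3000
warm-up (about 2.5 minutes) to verify Rhat <= 1.01 and ESS >= 400, while
the site-specific gradients themselves mix well already at the default
length.

`selection_gradients()` forms the xeric gradient from the base seed-mass
slope and the mesic gradient by adding the interaction, draw-wise, and
summarizes posterior means, central 95% and 80% intervals, the posterior
probability of a negative gradient, and the mesic-minus-xeric difference.
`posterior_predictive_check()` replicates datasets from the fitted model
(fresh random effects from their posterior hyperparameters, observed
seedling covariate kept for the adult submodel) and reports mid-p
posterior predictive p-values for the mean, variance and zero fraction of
each response; the mid-p correction (`Pr(T_rep > T_obs) + Pr(=)/2`) keeps
the discrete zero-fraction statistic calibrated when the observed value
sits on the support boundary.

## Problem sizes and numerical conventions used by the tests

Unit and acceptance tests run at deliberate sizes: variance-component
recovery on a 20-ecotype x 5-cluster x 10-genotype x 3-block panel
(empirical draws); the gradient coverage study at the full 294-plot design
with 40 simulated datasets and single chains of 2400 iterations (coverage
of the 95% intervals is ~0.95, bias ~0.01); null calibrations with 200–400
replicates. Tolerances follow the quantity: 1e-8 against algebraic
oracles, 1e-6 for REML vs closed forms, ±0.05 on recovered variance
proportions, ±0.1 on recovered gradients. Ties and degenerate inputs are
errors with classed conditions (`ecosel_*_error`) rather than silent
recoveries; zero-variance inputs, single-group designs, all-zero cells and
rank-deficient predictor sets all abort with the offending columns or
groups named.

## Known limitations

- With three ecotype levels the ecotype-level variance (and hence its
  proportion) is intrinsically weakly identified; bootstrap intervals for
  it are wide and often touch zero. This is a property of the design, not
  of the estimator.
- The common-slope test cannot detect pure sign reversals of the SMA slope
  (see above).
- The Poisson GLM stage reports, but does not correct, overdispersion; the
  hierarchical model is the package's answer to it.
- The truncated generator and the untruncated fitted model agree only in
  regimes where truncation rarely binds; pushing the adult gradients to
  extreme values moves the data out of that regime by design.
- The sampler is exact but not efficient; budget longer chains (or more
  chains) when effective sample sizes of the correlation and
  seedling-covariate parameters matter.
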