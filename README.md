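# ecosel

Statistical pipeline for studying **ecotypic divergence and local
adaptation through seed mass** in perennial grasses, built around two
experimental designs: a common-garden diversity panel (genotypes from
several population clusters grown in replicate blocks) and a reciprocal
seed-addition field experiment (seeds of each genotype sown at a xeric and
a mesic site, seedlings and adults censused per plot).

It is written for evolutionary ecologists asking the questions such
designs answer:

1. **How is trait variation arrayed across levels of genetic
   organization?** Canonical (linear) discriminant analysis of
   genotype-mean traits by ecotype (`lda_fit`), and nested
   variance partitioning — genotype within population cluster within
   ecotype — with genotype-level case-bootstrap confidence intervals
   (`fit_nested_ranef`, `bootstrap_proportions`).
2. **Does climate of origin predict seed mass?** All-subsets model
   selection over seven standardized climate/geography predictors with
   AICc, full (zero-substituted) model averaging over the ΔAICc < 7 set,
   and the marginal R² of the global mixed model (`all_subsets`,
   `model_average`, `marginal_r2`).
3. **Do ecotypes differ in seed-mass allometry?** Standardized major axis
   regression per ecotype with the among-group common-slope
   likelihood-ratio test (`sma_fit`, `common_slope_test`,
   `sma_by_ecotype`).
4. **Are ecotypes locally adapted?** Poisson GLMs of seedling and adult
   recruitment with ecotype × site interaction, likelihood-ratio term
   tests, Pearson goodness of fit and within-ecotype site contrasts
   (`fit_poisson_glm`, `term_tests`, `site_contrasts`).
5. **How strong is selection on seed mass at each site?** A joint
   hierarchical Bayesian model of both counts — Poisson, log link — with
   correlated plot effects, nested genotype effects, and site-specific
   selection gradients on standardized seed mass (`log_posterior`,
   `sample_posterior`, `selection_gradients`).

A synthetic-data generator (`simulate_panel`, `simulate_field`) reproduces
the two designs with known generative parameters — 123 genotypes × 3
blocks; 21 genotypes × 7 replicates × 2 sites × 100 seeds — so every stage
is testable by parameter recovery.

## The model at the core

For plot *i* with standardized genotype seed mass *z* and site indicator
*m* (mesic; xeric is the reference):

```
S_i ~ Poisson(exp(α_S + β z_i + β_site m_i + β_int z_i m_i + u_Si + v_S[g]))
A_i ~ Poisson(exp(α_A + γ_s S'_i + γ z_i + γ_site m_i + γ_int z_i m_i + γ_s:site S'_i m_i + u_Ai + v_A[g]))
(u_Si, u_Ai) ~ N2(0, Σ),   v ~ N(0, σ_v²)
```

with S′ the seedling count scaled by its SD, Σ a 2×2 covariance with
correlation ρ (the device that ties adult to seedling counts within a
plot), priors N(0, 25) on slopes, N(0, 10) on intercepts, half-t(3, 0, 10)
on random-effect SDs. The **xeric selection gradient** is β; the **mesic
gradient** is β + β_int; both are per standard deviation of seed mass on
the log-count (fitness) scale. MCMC runs 3 chains × 4000 iterations by
default (first half warm-up) with split-chain Rhat and ESS diagnostics.

## Worked example

```r
library(ecosel)

pan <- simulate_panel(panel_config(seed = 42))
gm  <- genotype_means(pan$traits)

lda_fit(gm[, c("seed_mass","germination_time","germination_pct","shoot_length",
               "root_length","flowering_time","seed_number","aboveground_biomass")],
        gm$ecotype)
#> Canonical discriminant analysis
#>   groups: lowland, sympatric, upland
#>   axes: 2; discrimination share: 95.8%, 4.2%
#>   resubstitution accuracy: 88.6%

variance_proportions(fit_nested_ranef(pan$traits, "seed_mass"))
#> Variance partition for seed_mass
#>            ecotype population genotype residual
#> variance    0.1447     0.0144   0.0808    2e-04
#> proportion  0.6026     0.0602   0.3365    7e-04

avg <- model_average(all_subsets(fit_global_lmm(pan$traits, pan$climate)))
avg[avg$predictor == "mat", c("averaged_coef","unconditional_se","p")]
#>   averaged_coef unconditional_se p
#> 4       -0.3691           0.0352 0

fg  <- select_field_genotypes(gm, 3, seed = 42)
fld <- simulate_field(field_config(seed = 42), fg)
post <- sample_posterior(selection_data(fld$plots, fg), seed = 42)
selection_gradients(post, "seedling")
#> Seed-mass selection gradients (seedling recruitment, per SD):
#>   xeric  +0.230 [95% CI +0.121, +0.343]  Pr(<0) = 0.00
#>   mesic  -0.532 [95% CI -0.651, -0.412]  Pr(<0) = 1.00
#>   mesic - xeric: -0.762 [-0.862, -0.663]
```

Reading the output: the first canonical axis carries almost all of the
among-ecotype discrimination, and seed mass is its dominant trait;
ecotype is the largest variance component for seed mass while most other
traits are dominated by genotype; among the seven climate predictors only
mean annual temperature is a significant predictor of seed mass (here
−0.37 mg per SD of MAT; the generator's target is −0.28); and selection
on seed mass points in opposite directions at the two sites — positive
(favouring large seeds) at the xeric site, negative at the mesic site —
with the generating values (+0.20, −0.56) inside both credible intervals.
That site reversal is the signature of local adaptation through seed size.

## Package layout

- `R/io.R` — table schemas, validation, CSV round-trip, standardization
- `R/synthetic.R` — the two generators and their configurations
- `R/lda.R`, `R/varcomp.R`, `R/climate.R`, `R/sma.R`, `R/recruitment.R`,
  `R/selection.R` — the six analysis stages
- `vignettes/ecotype-seed-mass-selection.Rmd` — models, assumptions,
  numerical conventions and design choices
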