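# socnetage

Age-related change in social network integration, from focal-follow
grooming observations to permutation-tested additive mixed models.

## The problem

In long-lived group-living animals — here, a community of adult
chimpanzees followed over seven or more years — a central question of
social gerontology is whether individuals disengage from their social
network as they age, and whether apparent age effects are really driven
by the things that change *with* age: dominance rank and, for females,
reproductive status. The raw data are annual dyadic grooming rates,

    rate(a -> b) = grooming minutes a gave b / minutes a and b shared a party,

from which annual weighted grooming networks are built in three sex
compositions (mixed-sex, males only, females only). Each individual-year
gets seven integration measures: in/out-degree and in/out-strength on the
directed network (social attractivity and effort), and weighted
betweenness (with edge cost `1/weight`), Barrat local transitivity and
eigenvector centrality on the undirected network (social roles and
embeddedness).

Each measure is modeled with penalized-spline additive mixed models
(GAMMs, via mgcv, REML), e.g. for mixed-sex networks

    metric ~ sex + s(age, by = sex, k) + s(rank, by = sex, k) + s(ID, bs = "re"),

in three model sets: rank-controlled, swelling-controlled (females), and
age-only. Because network positions are not independent, significance
comes from **node-randomized permutations**: node attributes are shuffled
across network positions within each year (and sex), models are refitted,
and the observed smooth-term F statistic is located in the null
distribution — a term is significant when it exceeds at least 95% of,
by default, 1000 null statistics. Stable individual differences
(repeatability) are measured as `ide`, the deviance explained by the
individual-identity random effect, tested the same way. Comparing the
age-only with the covariate-controlled models classifies each age effect
as independent, rank-mediated, swelling-mediated, or absent.

A synthetic focal-follow generator with known ground truth (38 adults,
22 females and 16 males, aged 12–57, 7 annual networks, skewed positive
rates, males more gregarious, stable individual differences) makes the
whole pipeline testable: size, power, repeatability recovery, and
reproduction of qualitative aging patterns.

## Worked example

```r
library(socnetage)

# simulate a community under the default study conditions
ds <- simulate_dataset(sim_config(seed = 1121))

# annual networks and the seven integration measures
metrics <- compute_metrics(ds$observations, ds$roster)
aggregate(cbind(out_strength, eigenvector_centrality) ~ sex,
          subset(metrics, composition == "mixed"), mean)
#>   sex out_strength eigenvector_centrality
#> 1   F    0.1923014              0.2273466
#> 2   M    0.4149826              0.5462066

# rank-controlled GAMM of out-strength, mixed-sex network
spec <- model_spec("out_strength", "mixed", "both_sexes",
                   include_rank = TRUE, set = 1)
fit <- fit_model(metrics, spec)
fit
#> gamm_fit (gam, gamma_log): out_strength, n = 266, deviance explained = 0.821
#>          term   edf ref_df statistic
#>   s(age):sexF  1.00   1.00    1.5809
#>   s(age):sexM  1.00   1.00    5.2279
#>  s(rank):sexF  1.00   1.00    0.1733
#>  s(rank):sexM  1.28   1.48    0.0542
#>         s(id) 32.46  36.00   16.9465

# node-permutation significance of the female age effect
permutation_test(metrics, spec, sex = "F", n_perm = 200, seed = 1)
#> perm_result: s(age):sexF | observed 1.529, percentile 75.5 over 200
#> permutations -> not significant

# repeatability of out-strength
ide(metrics, spec)
#> repeatability: ide = 0.381, variance ratio = 0.716
```

Read: males are roughly twice as strongly connected as females (the
built-in sex difference); under this null-age configuration the female
age smooth sits inside its permutation null (percentile 75.5, below the
95 threshold), while individual identity explains a large, stable share
of variation (`ide` 0.38 — individuals differ consistently in grooming
effort).

The numbered scripts under `analysis/` run the same steps over a saved
dataset — simulate, build networks, compute metrics, full inference with
mediation and repeatability, calibration experiments — writing tables
under `results/`.

## Package layout

| Path | Contents |
|------|----------|
| `R/sim-config.R`, `R/simulate.R` | synthetic focal-follow generator with ground-truth effects |
| `R/networks.R` | dyadic rates, annual network construction, exports |
| `R/metrics.R` | the seven integration measures (igraph-backed) |
| `R/models.R` | model specs, GAMM fitting, family choice, repeatability |
| `R/permutation.R` | node permutation, significance tests, mediation rules |
| `R/pipeline.R` | end-to-end orchestration, validators, summary table |
| `analysis/` | numbered drivers for the full analysis over saved data |
| `vignettes/social-aging-networks.Rmd` | methods: models, conventions, generator, experiments |
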