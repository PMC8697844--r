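---
title: "Measuring social aging in weighted grooming networks"
author: "socnetage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring social aging in weighted grooming networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socnetage)
```

## The problem

Long-lived social animals often change how they are embedded in their
group's social network as they age, and in humans shrinking networks are a
major health risk factor. In a fission--fusion primate community the raw
material for studying this is focal-follow data: minutes of grooming given
between each ordered pair of individuals in a year, and the minutes the
pair spent in the same party (the exposure during which grooming was
possible). The analytical difficulty is threefold:

1. network positions are not independent observations, so ordinary
   regression p-values are invalid;
2. age effects on sociality are expected to be non-linear (rank careers
   and reproductive schedules peak and decline), so linear age terms are
   inadequate; and
3. apparent age effects may really be effects of dominance rank or of
   female reproductive status, both of which change with age.

`socnetage` implements a complete pipeline for this inference problem:
annual weighted grooming networks in three sex compositions (mixed-sex,
males only, females only); seven node-level integration measures;
penalized-spline additive mixed models (GAMMs) of each measure against
age, rank and the proportion of time a female displays maximal sexual
swellings, with individual identity as a random intercept; node-permutation
significance tests; repeatability of individual differences; and a
mediation classification that separates intrinsic age effects from
status-driven ones. A synthetic-data generator with known ground truth
makes every stage testable.

## From observations to networks

The dyadic rate for actor $a$ and receiver $b$ in year $y$ is

$$ r_{ab} = \frac{\text{grooming minutes } a \to b}{\text{co-party minutes of } (a,b)} , $$

a dimensionless minutes-per-minute quantity. Dyads with zero (or
sub-threshold, see `min_exposure`) co-party time have an undefined rate
and are omitted; the default threshold is zero because the field protocol
gives no dyadic observation floor. Networks contain *all* resident members
of the composition in that year -- presence, not interaction, defines
membership, so socially inactive individuals are retained as isolates.
Directed edges carry $r_{ab}$; the undirected edge weight of a dyad is the
*sum* $r_{ab} + r_{ba}$. Summation (rather than the mean) preserves total
grooming volume; the two differ only by a global factor of 2, which every
implemented metric except the absolute strength scale is invariant to.

## The seven integration measures

Degree and strength are computed on directed networks: in-degree and
in-strength count partners and summed rates of grooming received
(attractivity), out-degree and out-strength of grooming given (social
effort). The remaining measures use undirected weighted networks:

* **Betweenness** -- the number of shortest paths between other member
  pairs passing through ego, ties fractionally counted, endpoints
  excluded, unnormalized. Grooming rates are affinities, not costs, so an
  edge of weight $w$ is traversed at cost $1/w$: stronger ties make
  shorter paths. This transform is the single most consequential
  convention in the metric layer and is configurable
  (`transform = "linear"` uses $\max w - w + \min w$); permutation
  percentiles are invariant to any monotone choice, but raw betweenness
  values are not comparable across conventions.
* **Local transitivity** -- the Barrat weighted clustering coefficient
  $$ c_i = \frac{1}{s_i (k_i - 1)} \sum_{(j,h)} \frac{w_{ij} + w_{ih}}{2}
     a_{ij} a_{ih} a_{jh} , $$
  the (strength-weighted) proportion of ego's partners that also groom
  each other. Egos with fewer than two partners have no defined value;
  such rows are dropped listwise for transitivity models only.
* **Eigenvector centrality** -- the principal eigenvector of the weighted
  adjacency matrix, rescaled to a maximum of 1. It is computed on the full
  graph; members of minor disconnected components get numerically zero
  scores, and an edgeless network yields all zeros with a warning.

Every metric is verified in the test suite against an independent
brute-force oracle on hundreds of small random graphs: strengths against
adjacency row/column sums, betweenness against Floyd--Warshall distances
with explicit shortest-path counting (itself validated against raw path
enumeration), transitivity against a literal triple loop, eigenvector
centrality against dense eigendecomposition.

## The additive mixed models

Each integration measure is a response in penalized-spline GAMMs fitted by
restricted maximum likelihood. Three model sets mirror the study design:

| Set | Composition | Linear and smooth terms |
|-----|-------------|--------------------------|
| 1 (rank-independent) | mixed | `sex + s(age, by = sex, k) + s(rank, by = sex, k)` |
| 1 | same-sex | `s(age, k) + s(rank, k)` |
| 2 (swelling-independent, females) | mixed | `s(age, k) + s(rank, k) + s(time_swollen, k) + ti(age, time_swollen)` |
| 3 (general age effects) | mixed | `sex + s(age, by = sex, k)` |
| 3 | same-sex | `s(age, k)` |

All models carry `s(id, bs = "re")`, a ridge-penalized random intercept
for individual identity. The tensor interaction `ti(age, time_swollen)`
has its marginal effects removed, so it captures only the
age-by-reproductive-status interaction (older females in estrus may be
differentially attractive). Families are Gaussian, or Gamma with a log
link when the response is strictly positive and right-skewed (moment
skewness above 1); responses containing zeros -- strengths of isolates,
betweenness -- are always Gaussian because a Gamma likelihood is
inadmissible at zero. The choice is logged and can be overridden per
model.

Basis dimension defaults to `k = 5` per univariate smooth (4 per margin of
the tensor term inside the pipeline). We deliberately fix defaults rather
than auto-optimize per model: the original protocol tuned `k` per fit with
residual diagnostics, but an automatic optimizer inside a permutation loop
would make null statistics incomparable across refits. Five basis
functions are enough for the monotone, single-peak and
rise-then-plateau shapes that age trajectories take at these sample sizes.

Two fitting engines are exposed: exact REML (`gam`, the default for
reported fits) and fast discretized fREML (`bam`), used inside permutation
sweeps where thousands of refits are needed. Within any one test the
observed and null statistics always come from the same engine.

### Repeatability

Stable individual differences are quantified as `ide`, the drop in
deviance explained when the identity intercept is removed, both fits on
identical rows. The variance-components ratio
$\sigma^2_{id} / (\sigma^2_{id} + \sigma^2_{\varepsilon})$ is reported
alongside; for Gamma-log models the residual variance is taken on the
link scale as $\psi_1(1/\phi)$ (the trigamma variance of a log-Gamma
variate with dispersion $\phi$). The deviance-based `ide` is the headline
number and the permutation statistic, because it is defined identically
for both families; the ratio is the Gaussian-interpretable check. Results
are flagged when either fit fails to converge or when individuals are
observed only once (identity then confounded with residual).

## Node-permutation inference

Significance comes from node-randomized permutations: within each year
(and within sex, whenever the model contains sex or by-sex terms), the
intact blocks of node attributes -- identity, sex, age, rank, time swollen
-- are reassigned uniformly at random to the network positions' metric
values. Metric values never move, so network structure is exactly
preserved and only the attribute-to-position mapping is broken. Because
node-level metrics are invariant to vertex relabeling, this is equivalent
to permuting node labels on the network before computing metrics, at a
small fraction of the cost.

Sex stratification is the default restriction (configurable): it keeps
each sex's attribute blocks on same-sex network positions, so the null
model targets age and identity structure rather than the sex composition
of positions. Permuting within year (not across the pooled longitudinal
table) is the conservative reading of a node-randomization design for
annual networks.

The reported percentile is the percentage of null statistics the observed
statistic is *strictly greater than* (ties count against significance);
a term is significant when its percentile reaches the threshold,
default 95. Statistics are the Wood-type approximate F of each smooth, and
`ide` for repeatability; both are one-sided by construction. The default
is 1000 permutations; the calibration and power experiments in the test
suite use 100 to keep desk-scale runtimes, which widens the percentile
granularity but does not bias the size of the test. Non-convergent
permutation refits are dropped and logged; the permutation count refers to
successful refits.

### Mediation

For each (response, sex, composition) cell the pipeline compares the
general age model (set 3) with the covariate-controlled models (sets 1
and 2): an age effect significant in both is *covariate-independent*; one
that disappears under control while the covariate itself is significant is
*mediated* by rank or swelling; no general age effect means *no age
effect*; the residual pattern (effect lost but covariate not significant)
is conservatively labeled no age effect, with a note. A female mixed-sex
age effect must survive both the rank and the swelling control to count
as independent.

### Direction tokens

Significant age smooths are classified on a 50-point grid over the
observed age range: monotone (to 0.1% of the fitted range) up or down is
`increase`/`decrease`; an interior maximum whose terminal value sits more
than 10% of the fitted range below the peak is `peak_then_decline`;
an interior rise whose terminal value stays within 10% of the peak is
`rise_then_plateau`. The 10% operationalization of "plateaus" is an
invented but configurable threshold (`tol_frac`); non-significant terms
are always `none`.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions: 22 females and 16
males aged 12--57, present in all of 7 annual windows and aging by exactly
one year between windows. Ranks are within-sex, within-year percentiles of
a latent quality that peaks in mid-adulthood for males (cooperative rank
careers) and rises monotonically with age for females (queue-like ascent),
each with a stable individual component. Female time swollen declines with
age in expectation; males are structurally zero.

Grooming is generated on the rate scale with a log-linear mean:
baseline rate (default $e^{\log 0.008} = 0.8\%$ of co-party time), stable
actor-side ("sociality") and receiver-side ("attractivity") individual
intercepts (centered; SD 0.45 and 0.35 on the log scale), per-sex
age-effect functions on both the actor and the receiver side, and dyad
sex-class offsets ordered MM > MF = FM > FF so that males are the more
gregarious sex. Minutes are Gamma around mean rate x exposure
(dispersion 1: strongly right-skewed, as real rate data are), capped at
the exposure. Co-party minutes are lognormal around 6000 min/year,
symmetric within a dyad, with a 5% chance of structural zero (pairs that
never share a party). An edge-presence stage (logit baseline 0.45, shifted
by the same log-mean predictors) makes networks realistically incomplete
-- mean directed degree around 15--18 of 37 -- and lets gregarious
individuals hold more partners, not just stronger ties. The observed
totals behind these scale choices are reported only as annual means in the
field literature; the generator emulates scale and skew, not the
minute-by-minute mechanism, and none of its rate parameters are calibrated
to a specific community.

Age effects are quadratic on the log scale by default (in scaled age
$z \in [-1, 1]$), which covers the monotone and peak-then-decline
shapes of interest; arbitrary functions of age can be supplied. The named
levers used by the experiments:

* `age_effect_out_female = c(-0.7, -0.15)` -- a moderate decline in
  female grooming effort (oldest females give roughly half the grooming
  of average-age females) driving falling out-strength;
* `age_effect_in_male = c(0.15, -1.5)` -- a concave receiver-side male
  effect producing the mid-adulthood peak in male in-strength and
  sustained embeddedness;
* `cross_sex_age_effect_male` -- a log-scale slope applied only to
  mixed-sex dyads in the male member's age; negative values make older
  males disengage from females specifically, which raises their local
  transitivity in the mixed-sex network (their remaining, mostly male,
  partners groom each other) while leaving same-sex networks untouched.

What the generator does *not* emulate: focal-follow sampling effort and
observer imbalance, party-scan structure, kinship, immigration/death
(every individual is present in all years), or temporal autocorrelation
within years. Passing recovery tests therefore demonstrates that the
inference machinery recovers known effects from data with realistic
scale, skew, sex structure and repeatability -- not that it is robust to
every field-data pathology.

## Calibration and recovery experiments

The acceptance layer (`tests/testthat/test-acceptance.R`, reproducible via
`scripts/acceptance.R`) computes:

* **Size**: on 200 null datasets (20 individuals x 5 years, no age or
  identity effect) the rejection rate at threshold 95 with 100
  permutations must be statistically compatible with 0.05.
* **Power and direction**: the injected female out-strength decline is
  detected (percentile >= 95) in at least 80% of 20 community
  simulations, labeled `decrease`, while the same cell under the null
  configuration fires in at most 10%.
* **Repeatability**: at ICC 0.5 (38 x 7, Gaussian) the variance ratio is
  recovered within 0.15 and identity tests significant in at least 90% of
  seeds; at ICC 0 the mean `ide` stays below 0.05 with at most 10%
  significance.
* **Pattern reproduction**: under the three-lever configuration above,
  the pipeline's summary must reproduce male `peak_then_decline`
  in-strength (same-sex), male `increase` in transitivity in the
  mixed-sex network only, and female `decrease` in out-strength
  (mixed-sex), each in a majority of seeds.

Problem sizes in these experiments (100--200 permutations, 5--20 seeds,
200 calibration datasets) are chosen so the whole suite runs on a single
CPU at desk scale; the permutation-size calibration feeds the model the
direct null-response generator rather than the full grooming simulator,
whose null behavior is exercised separately by the power experiment's
null arm.

## Numerical and degenerate-input conventions

* Eigenvector centrality pins its iterative solver's start state so
  repeated calls are bit-identical, and restores the caller's RNG stream.
* Zero-variance responses return a degenerate fit (all term statistics 0,
  zero deviance explained) rather than an error, so constant metrics
  yield percentile 0 and "not significant".
* Non-finite term statistics are mapped to 0 (they arise only in the
  degenerate-variance case).
* Permutation groups with fewer than two rows are left unpermuted with a
  warning; a permutation refit that does not converge is dropped, and a
  warning fires when more than 10% fail.
* Ties between observed and null statistics count as not exceeded.
* `choose_family` needs at least 10 non-missing values and falls back to
  Gaussian (with a warning) on constant input.

## Known limitations

Raw betweenness values depend on the affinity-to-distance convention;
only their permutation percentiles are convention-free. The concurvity
between age, rank and time swollen is handled by the penalized fits but
not diagnosed beyond the design (no concurvity indices are computed).
The mediation labels are pattern classifications over three significance
calls, not causal mediation estimands. `ide` is reported both as a
deviance difference and a variance ratio because the two coincide only in
balanced Gaussian settings; the deviance version is the one permuted.
Finally, percentiles from 100-permutation runs are granular to 1 point;
use 1000 permutations for reportable results.
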