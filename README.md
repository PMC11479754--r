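# lansing

Demographic analysis of the **Lansing Effect** — the tendency of offspring
of older parents to live shorter lives than offspring of younger parents —
from daily cohort census data.

Comparing two groups' mean lifespans shows *that* they differ; fitting
explicit mortality-trajectory models shows *how*. Offspring of old parents
may start life frailer (higher mortality at every age — a larger initial
mortality parameter *a*) or may age faster (hazard rising more steeply — a
larger mortality-rate parameter *b*). This package implements a two-stage
model-selection analysis that separates the two, plus resampling inference
for fitness-related life-history traits. It is aimed at demographers and
evolutionary biologists with longitudinal cohort data in which each
individual is observed daily from birth to death.

## The models and the analysis

Four mortality families are fitted to integer lifespans by
interval-censored maximum likelihood (an individual recorded at day *L*
died in *[L, L+1)*):

- exponential: *l(t) = e^(−at)*
- Gompertz: *l(t) = exp(−(a/b)(e^(bt) − 1))*
- Weibull: *l(t) = exp(−(at)^b)*
- logistic: *l(t) = (1 + (ac/b)(e^(bt) − 1))^(−1/c)*

where *a* is the initial mortality, *b* the rate of demographic ageing,
and *c* the heterogeneity/deceleration parameter (late-life plateaus;
*c* → 0 recovers Gompertz).

**Stage 1** selects among the four families for each group separately by
AICc (= −2ℓ + 2k + 2k(k+1)/(n−k−1)) and Akaike weights
*w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2)*.
**Stage 2** fits the two groups *jointly* under all 2³ = 8 logistic
candidates in which each of (*a*, *b*, *c*) is independently common or
distinct between groups (capital letter = distinct: `Abc` has distinct
*a*, common *b*, *c*), localizing the survival difference.

Companion tools: randomization tests and stratified bootstrap CIs for
lifespan, age at first reproduction, total offspring and the intrinsic
rate of increase *r* (log of the dominant eigenvalue of an
individual-level Leslie matrix, cross-checked against the Euler–Lotka
root); bootstrap confidence bands for fitted survival curves; and a
synthetic two-cohort generator emulating a duckweed parental-age study for
end-to-end rehearsal.

## Worked example

```r
library(lansing)

# Akaike weights from a published joint selection table's delta-AICc column
signif(akaike_weights(c(0.00, 2.02, 2.17, 2.74, 3.82, 5.48, 69.73, 77.95)), 3)
#> [1] 4.61e-01 1.68e-01 1.56e-01 1.17e-01 6.83e-02 2.98e-02 3.33e-16 5.46e-18

# End-to-end on a synthetic cohort: two groups, 10-fold contrast in
# initial mortality a, common b and c
cfg <- cohort_config(n = c(first = 120, fifth = 120), seed = 42)
res <- run_full_pipeline(cfg, n_permutations = 2000, n_boot_ci = 2000,
                         n_boot_params = 200)
res
#> two-stage demographic analysis (first vs fifth), seed 42
#>
#> stage 1 best families: first = logistic, fifth = logistic
#> stage 2 best joint candidate: 'Abc' (Akaike weight 0.446)
#>
#> trait contrasts (first - fifth):
#>   lifespan         +7.2  [5.516, 9.034]  p = 0.0004998
#>   age_first_repro  +0.7333  [0.3, 1.117]  p = 0.0009995
#>   total_offspring  +2.692  [1.733, 3.609]  p = 0.0004998
#>   r                -0.05188  [-0.07729, -0.02569]  p = 0.0004998
```

Reading the output: both groups are best described by the logistic family
(stage 1); jointly, the best candidate is `Abc` — the groups differ in
initial mortality *a* but share the ageing rate *b* and heterogeneity *c*
(stage 2). The first-offspring group lives ~7 days longer, starts
reproducing later and produces more offspring, yet has the *lower*
intrinsic rate of increase *r*: the short-lived group's earlier
reproduction outweighs its smaller lifetime output. Each contrast comes
with a stratified-bootstrap 95% CI and a two-sided randomization-test
p-value (add-one corrected, so never exactly 0).

Lower-level entry points: `fit_mortality()`, `select_models()`,
`fit_mortality_joint()`, `joint_model_selection()`, `cohort_summaries()`,
`leslie_r()`, `permutation_test()`, `bootstrap_mean_diff()`,
`bootstrap_model_params()`, `survival_band()`, `read_cohort()` /
`write_cohort()`.

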