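# mrdsurvey

Abundance estimation for stratified line-transect aerial surveys with two
independent observer teams — mark-recapture distance sampling (MRDS).

Conventional distance sampling assumes every animal sitting on the transect
line is seen (g(0) = 1). For aerial surveys of sparse Arctic wildlife that
assumption is shaky: animals directly under the aircraft can be missed. The
MRDS protocol treats a front and a rear observer team as two capture
occasions, so that detection *on the line* can be estimated rather than
assumed. This package implements that analysis end to end for cluster-living
species, motivated by on-ice helicopter surveys of polar bears (*Ursus
maritimus*) in the Kane Basin region, whose published summary tables ship as
built-in fixtures (`kb_*()` functions).

## The model

**Double-observer stage.** For detected cluster *i* and observer position
*pos* ∈ {F, R},

```
logit(p_i,pos) = b0_pos + b1 d_i [+ b2 X_i]
```

with position-specific intercepts, a shared perpendicular-distance slope,
and at most one extra covariate (squared distance, cluster size, activity,
ice structure, visibility, cloud cover, a rear-observer blind-spot indicator
for d ≤ 75 m, or a position-specific slope) — nine candidate models ranked
by AICc. Conditional on detection by at least one team, the capture history
(front-only, rear-only, both) is multinomial under full independence; the
probability that a cluster on the line is seen at all is

```
p0* = 1 - (1 - pF0)(1 - pR0).
```

**Distance-sampling stage.** Exact distances y within truncation w follow a
detection function g(y) built from a key (uniform, half-normal
exp(−y²/2σ²), hazard-rate 1−exp(−(y/σ)^−b)) and cosine / polynomial /
Hermite adjustment series, fitted by maximum likelihood with adjustment
terms chosen by forward AIC selection and checked by a Cramér–von Mises
test. The strip-mean detection probability is p_d = ∫₀ʷ g(y) dy / w.

**Abundance.** With p_a = p0* · p_d (delta-method variance), cluster
abundance is Horvitz–Thompson per stratum k, scaled by area over surveyed
strip area a_k = 2 w L_k:

```
C_total = Σ_k (A_k / a_k) c_k / p_a,    N = C_total · ḡ
```

where ḡ is mean cluster size. The variance decomposes additively into a
detection component (delta method per stratum), an encounter-rate component
(systematic transects treated as non-overlapping adjacent pairs with a
length-weighted between-transect estimator), and a cluster-size component
via the product rule; intervals are lognormal on the CV. Estimates are
model-averaged over supported detection models with Akaike weights, the
unconditional SE carrying model-selection variance.

A synthetic survey generator (`sim_config()`, `generate_survey()`,
`recovery_study()`) lays systematic transects over square strata, drops
Poisson clusters, and composes availability (the g(y) curve) with
observer-level logistic detection, so the whole pipeline can be exercised
against known truth.

## Worked example

```r
library(mrdsurvey)

d <- kb_survey_fixture()   # rebuilt from the published binned sightings
d
#> Line-transect survey: 28 detected clusters, 4 transects (4160 km), 2 strata
#> Truncation: 1400 m

fit_mr(d, "none")          # double-observer submodel, distance + position
#> Double-observer MR fit, spec 'none' (k = 3, n = 28)
#>   logLik -27.242  AICc 61.48
#>   pF0 0.849 (SE 0.099)  pR0 0.737 (SE 0.139)  p0* 0.960 (SE 0.044)

ds <- kb_ds_table()        # the four published detection functions
pd <- model_average(ds$pd, ds$se_pd, ds$weight)
mr <- kb_mr_table()
p0 <- model_average(mr$p0_star, mr$se_p0_star, mr$weight)
pa <- combined_pa(p0$estimate, p0$se^2, pd$estimate, pd$se^2)
sprintf("combined pa: %.3f (SE %.3f)", pa$estimate, pa$se)
#> "combined pa: 0.544 (SE 0.147)"

ab <- kb_abundance_table()
n4 <- model_average(ab$n_hat, ab$se_n_hat, ab$weight)
sprintf("model-averaged abundance: %.0f bears (SE %.0f)", n4$estimate, n4$se)
#> "model-averaged abundance: 190 bears (SE 75)"
lognormal_ci(n4$estimate, n4$se / n4$estimate)
#>       low      high
#>  90.06783 399.14259
```

Front observers saw 22 of 28 clusters and rear observers 16, so a cluster
on the line is seen with probability ~0.95 by at least one team; detection
averaged over the 1400 m strip is ~0.57, giving a combined inclusion
probability of ~0.54 and a model-averaged estimate of ~190 bears, with most
uncertainty coming from the detection-function stage.

`run_analysis()` chains every stage (truncation, both model sets,
averaging, stratified abundance, extrapolation) from a config list or YAML
file and writes table-style CSVs plus a JSON summary.

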