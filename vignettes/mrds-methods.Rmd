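---
title: "Mark-recapture distance sampling: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mark-recapture distance sampling: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrdsurvey)
```

# The estimation problem

Line-transect distance sampling estimates density from the perpendicular
distances of detected animals, under the convention that detection on the
line is certain. Aerial surveys of sparse, white-on-white Arctic wildlife
violate that convention often enough to matter, so the mark-recapture
distance sampling (MRDS) protocol flies two observer teams — front and rear
— that search independently. The rear team's detections of clusters the
front team missed (and vice versa) identify detection *on the line*; the
decline of detections with distance identifies detection *off the line*;
and their product gives each detected cluster's inclusion probability for a
Horvitz–Thompson estimate of abundance.

This vignette records the package's own account of each modelling stage:
the assumptions, the tunable parameters and their defaults, the numerical
choices, what the synthetic generator does and does not emulate, and the
known limitations.

# Double-observer submodel

Conditional on a cluster being detected at all, its capture history
$\omega_i \in \{10, 01, 11\}$ is multinomial with cell probabilities
$p_F(1-p_R)/p^*$, $(1-p_F)p_R/p^*$ and $p_F p_R/p^*$, where
$p^* = 1-(1-p_F)(1-p_R)$ and each team's probability follows
$\mathrm{logit}(p_{i,pos}) = \beta_{0,pos} + \beta_1 d_i\,[+\beta_2 X_i]$.
This is the full-independence configuration: the two teams are assumed not
to cue one another, matching a protocol in which each team gets an
unprompted opportunity to sight every cluster. Unmodelled heterogeneity
shared by both teams (weather pockets, cryptic postures) would bias $p_0^*$
upward; the covariate candidates (activity, ice structure, visibility,
cloud cover, squared distance, cluster size, a rear blind spot within 75 m,
a position-specific slope) exist to absorb the heterogeneity that was
measurable. With typical sample sizes of a few dozen clusters, at most one
extra covariate is allowed per model, giving nine candidates, ranked by
AICc with $n$ = detected clusters.

Numerical choices: distance enters the optimizer in kilometers (meters are
poorly conditioned against logit-scale intercepts); coefficients are
reported per meter. Optimization is BFGS from six deterministic starts
(null plus fixed offsets), relative tolerance $10^{-8}$; the covariance
matrix is the inverse observed information, and a singular information
matrix is reported as an error suggesting a simpler model rather than being
silently regularized. Fitting requires both asymmetries (some front-only
and some rear-only detections); without them the position intercepts sit on
the boundary and the fit is refused as non-identifiable.

Reported on-line probabilities for covariate models are the simple average
over detected clusters of each cluster's probability at distance zero with
its own covariates, and $p_0^*$ is the per-cluster average of
$1-(1-p_{F0,i})(1-p_{R0,i})$. For covariate-free models this reduces
exactly to plugging the intercepts into the formula above. A
Horvitz–Thompson-weighted average would be an alternative; the simple mean
was chosen because it reproduces the published covariate-model summaries
this design was checked against, and the difference is second-order at
these sample sizes.

The uninformative-parameter rule: a one-parameter addition whose AICc
improvement over the base model is less than 2 and whose coefficient has
$|z| < 1.28$ is flagged and excluded from model averaging — such a model
rides on the base model's likelihood rather than explaining anything.

Goodness of fit is a Pearson $\chi^2$ on capture-history counts within
distance bins. Because the conditional likelihood fixes each bin's total,
every retained bin contributes (cells − 1) degrees of freedom:
df = cells − bins − $k$. Cells with expectation below 2 are pooled within
their bin (smallest into next smallest); a bin still below 2 is folded into
its neighbour. Null simulations at $n = 250$ put the mean statistic within
a few percent of this df.

# Distance-sampling stage

Detection functions are the standard key-plus-series families,
$g(y) = \mathrm{key}(y)\,(1 + \sum_j a_j \mathrm{adj}_j(y/w))$ rescaled so
$g(0)=1$: uniform, half-normal, hazard-rate keys; cosine (orders 1, 2, …),
simple polynomial $(y/w)^{2j}$, and Hermite (half-normal only) series, all
standardized by the truncation width. With this convention the four
standard candidates carry 1 (uniform–cosine), 2 (hazard-rate), 1
(half-normal) and 1 (uniform–polynomial) parameters. Distances are treated
as exact — the likelihood is $\sum_i \log[g(y_i)/\mu]$ with
$\mu = \int_0^w g$ — because the survey protocol measures them by GPS
rather than by binning.

Defaults: right truncation $w = 1400$ m and no left truncation; adjustment
terms are added one at a time while AIC strictly decreases; cluster size as
a scale covariate is implemented but off by default (it consistently
worsened AIC in the motivating survey). $g$ is constrained to $[0, 1]$ on a
1000-point grid by a penalty — nonnegativity because $g$ is a probability,
the upper bound because the series expansion can otherwise overshoot 1
between grid points of support; monotonicity is deliberately *not*
enforced, matching standard practice. The integral $\mu$ uses adaptive
quadrature at relative tolerance $10^{-8}$ with a deterministic 2048-point
Simpson fallback, verified in tests against a $10^6$-point Riemann sum.
One-parameter fits use Brent's method; multi-parameter fits use
Nelder–Mead, because the feasibility penalty is a cliff that
finite-difference gradients cannot cross.

Fit is assessed with the Cramér–von Mises statistic on the fitted distance
CDF, with p-values from the classical Bessel-series expansion of the
asymptotic null distribution. Since parameters are estimated from the same
data, the test is mildly conservative; null simulations at the motivating
survey's sample size ($n = 28$) reject at rate ≤ 5% at the 5% level.

# Model averaging and abundance

Ranking uses AICc for the double-observer stage and AIC for the
distance-sampling stage. Models within 4 criterion units of the best and
not flagged uninformative are averaged with Akaike weights, always
renormalized over the averaged subset; the unconditional standard error is
$\sum_i w_i \sqrt{v_i + (\hat\theta_i - \bar\theta)^2}$, so selection
uncertainty enters the variance budget explicitly.

Abundance applies a single $p_a = p_0^* \hat p_d$ and a single mean cluster
size across strata — the right constraint when one stratum contributes a
handful of detections — while encounter rates differ by stratum. The strip
area is $a_k = 2 w L_k$ with $w$ in km. Encounter-rate variance treats the
systematically placed transects, ordered by design position, as
non-overlapping adjacent pairs (a trailing triple when the count is odd)
with a length-weighted between-transect estimator inside each group;
overlapping pairs would be an alternative reading of "adjacent transects as
paired samples", and the grouping lives in one function
(`encounter_var_s2()`) precisely so it can be swapped. The encounter
component is scaled to the stratum total holding $(A_k/a_k)/p_a$ fixed,
because detection uncertainty is already counted in the delta-method
component and would otherwise be double-counted. Intervals are lognormal,
$N / C$ to $N \times C$ with $C = \exp(z\sqrt{\ln(1+\mathrm{cv}^2)})$ and
$z = 1.96$; on the motivating survey's inputs this gives 90–399 for a point
estimate of 190 at CV 0.39, where the original report printed 87–411 —
consistent with a heavier-tailed (e.g. t-based) variant whose exact form
was not stated; interval endpoints should therefore not be over-read at
this precision.

Degenerate inputs: zero detections in every stratum, $p_a \le 0$, and
single-transect strata are errors, not NaNs; a stratum with zero detections
but two or more transects is fine (it contributes zero encounter variance
and zero clusters).

# The synthetic generator

`generate_survey()` emulates the motivating design: each stratum is a
square of the stated area, transects run across it at the design spacing
from a uniform random start (so the expected transect count is
side/spacing), and cluster centers follow a homogeneous Poisson process
with intensity density/mean-cluster-size. Detection composes two stages:
availability with probability $g(y)$ (half-normal, scale 700 m by default,
strip-mean ≈ 0.6), then independent observer-level detection with logistic
curves (defaults: on-line probabilities 0.84 front / 0.73 rear, shared
slope −1.2 per km). The union probability is $g(y)\,p^*(y)$; availability
cancels from the conditional capture-history likelihood, so the
double-observer stage consistently estimates the logistic curves, while the
distance-sampling stage sees the product shape. Default strata are
18,870 km² at 10 bears/1000 km² (6 km spacing) and 9,110 km² at
1.7 bears/1000 km² (18 km spacing), truncation 1400 m, cluster sizes 1:2:3
in proportions 13:9:6 — the motivating survey's composition — giving ≈ 200
bears of truth and ≈ 25 detected clusters per replicate, the realistic
hard regime.

What it does not emulate: spatial density gradients and autocorrelation
(clusters are CSR within strata), responsive movement, fjord-constrained
transect geometry, ferry flights, measurement error in distances, and
covariate-dependent detection (the recorded covariates are independent
noise by default). Passing recovery tests therefore demonstrates that the
estimator chain is correct *under its own assumptions* — unbiasedness under
perfect detection, near-nominal interval coverage under imperfect detection
at survey-like sample sizes — not that any particular field survey is free
of assumption violations.

Problem sizes used in the shipped tests were chosen to make Monte-Carlo
error small relative to the property being checked: 200 replicates for
interval coverage (binomial MC error ≈ 1.6%), 500 for count expectations
and null calibrations, $n = 2000$ for single-fit parameter recovery.

# Known limitations

- The double-observer stage assumes full independence between teams;
  shared unmodelled heterogeneity biases $p_0^*$ upward. Point-independence
  variants are out of scope.
- With ~28 clusters, detection-function choice dominates the variance
  budget (the published survey's hazard-rate model alone moved the estimate
  by a third); the model-averaged interval is honest about this, but no
  amount of averaging substitutes for the 60–80 detections usually
  recommended for stable detection functions.
- Per-stratum detection and cluster size are deliberately not estimable;
  surveys with ample detections per stratum would want that generality.
- The lognormal interval ignores estimation error in the CV itself
  (no Satterthwaite-style df), which is one plausible source of the
  discrepancy with the originally printed interval noted above.
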