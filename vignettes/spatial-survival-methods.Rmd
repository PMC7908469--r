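---
title: "Spatial frailty survival models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial frailty survival models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spfrail` fits a parametric proportional-hazards model with spatially
correlated, district-level log-Gaussian frailties to right-censored
registry survival data:

$$h(t_i) = h_0(t_i;\,\omega)\,\exp\{x_i^\top\beta + Y_{d(i)}\},$$

where $h_0$ is the baseline hazard, $x_i$ the covariate row of patient
$i$ (dummy-coded categoricals with explicit "Missing" levels, z-scored
continuous covariates), and $Y_{d(i)}$ the log frailty of the patient's
district. The frailty vector over the $m$ districts is multivariate
normal with exponential spatial correlation on centroid distances,

$$Y \sim N\!\big(-\tfrac{\sigma^2}{2}\mathbf{1},\;
   \sigma^2\,\exp(-d_{jk}/\phi)\big),$$

so that correlation decays to $e^{-1}$ at distance $\phi$ (metres) and
the multiplicative frailty $\exp(Y_j)$ has unit prior mean. With
right-censoring indicator $\delta_i$ the log-likelihood is
$\sum_i \delta_i\{\log h_0(t_i) + x_i^\top\beta + Y_{d(i)}\} -
H_0(t_i)\exp\{x_i^\top\beta + Y_{d(i)}\}$.

Three baseline families are supported: exponential ($h_0=\lambda$),
Weibull ($h_0=\alpha\lambda t^{\alpha-1}$), and a cubic B-spline on
$\log h_0$ with three interior knots at the 25/50/75% follow-up
quantiles (positivity by construction; $H_0$ by quadrature). Families
are compared by WAIC computed from the pointwise log-likelihood matrix
with log-sum-exp stabilisation. Time is measured in days; distances in
metres.

## Identifiability: the baseline/frailty ridge

The likelihood is exactly invariant to adding a constant $c$ to every
$Y_j$ while scaling the baseline by $e^{-c}$. Identification of the
level therefore comes entirely from the priors. Three design choices
deal with this:

1. **Frailty prior mean $-\sigma^2/2$**, so $E[\exp(Y_j)] = 1$ and the
   frailty field carries relative, not absolute, risk.
2. **Baseline priors centred at the non-spatial maximum-likelihood
   prefit.** Priors are normal on the log parameters with sd 2. A
   zero-centred mean is untenable for scales in day units (e.g. a
   Weibull rate-scale of $2\times10^{-5}$ sits more than 5 prior sds
   from zero), and a mis-centred baseline prior pushes the level into
   the frailty field, inflating $\sigma^2$ and $\phi$. Centring the
   prior at the prefit (the same convention used for the $\log\phi$
   prior mean, the log median inter-centroid distance) keeps the ridge
   anchored where the data put the non-spatial fit. Both are
   overridable.
3. **A level-transfer Metropolis move** that proposes
   $(Y + c\mathbf{1},\, \omega e^{-c})$ jointly. Because the likelihood
   is unchanged, the move is accepted on the prior ratio alone; it lets
   the chain traverse the ridge so the priors — not the starting point —
   allocate the level.

A second soft ridge is $(\sigma^2, \phi)$: under an exponential
correlation with range beyond the map diameter only the ratio
$\sigma^2/\phi$ is well identified, which is why the range is reported
with deliberately loose recovery expectations (a factor of 3) and why
the $\log\phi$ prior is weakly informative on the map's own scale.

## MCMC design

The sampler is blockwise adaptive random-walk Metropolis:

* $\beta$ and $\log\omega$ blocks: multivariate Gaussian proposals with
  Haario-style running-covariance shape and Robbins–Monro scale
  adaptation toward 0.234 acceptance (0.44 for scalar blocks).
* frailty field: *whitened* updates — proposals are made on
  $v = L^{-1}(Y-\mu)$ with $LL^\top = \Sigma$, i.e. in the
  Cholesky-decorrelated space, where the prior is standard normal.
* $(\log\sigma^2, \log\phi)$: a *centred* update that holds $Y$ fixed
  and accepts on the multivariate-normal density ratio of $Y$
  (determinant included). Interweaving the centred covariance update
  with the non-centred field update keeps both identified: a purely
  non-centred covariance update omits the determinant and lets
  $\sigma^2$ inflate when per-district event counts are high.
* the level-transfer move described above.

The frailty and covariance blocks cost $O(m)$ and $O(m^3)$ with
$m \ll n$, so they run several times per sweep (defaults 5 and 3).
Adaptation is frozen after burn-in, so the retained chain is Markovian.
All randomness flows through R's RNG: a seed makes chains bitwise
reproducible. Default full-scale settings are 110,000 iterations,
10,000 burn-in, thinning 10; validation runs use explicit smaller
settings (20,000 iterations suffice at $n \approx 2000$, $m = 50$).
Initial values: $\beta = 0$, $\omega$ from a `survival::survreg`
prefit, $v = 0$ (prior mean), $\sigma^2 = 0.1$, $\phi =$ median
inter-centroid distance. The sampler used by the original analysis is
gradient-based (MALA); the contract here is distributional correctness,
not algorithmic identity, verified by a conjugate gamma–exponential
check, prior-recovery runs with the likelihood switched off, and
parameter-recovery simulations.

Diagnostics: per-parameter effective sample size (Geyer initial
positive sequence), lag-1 autocorrelation, a Geweke-style mean-split
z-score, and a prior/posterior overlap statistic (integral of the
pointwise minimum of the two densities) whose value near 1 flags
weakly identified parameters.

## Area-level covariates

The socioeconomic index is observed for most districts and imputed at
the missing districts' centroids by **ordinary kriging** (unit-sum
weights via a Lagrange multiplier). The variogram is fitted by weighted
least squares (Cressie weights $n_j/\gamma_j^2$) over the candidate set
{exponential, spherical, gaussian} with the smallest weighted residual
picking the model — mimicking automatic variogram fitting. Defaults the
original tooling does not document and that are package choices: 15
distance bins, pair cutoff at half the maximum pairwise distance (long
enough to anchor the sill, which stabilises the range estimate), and
three optimiser starts to escape the nugget/short-range and
long-range/sill ridges.

Healthcare accessibility is proxied by an isotropic Gaussian-kernel
intensity of hospital locations evaluated at district centroids, in
hospitals per km². The default bandwidth is the 2-D normal rule of
thumb $\hat\sigma k^{-1/6}$; there is no edge correction by default.
Both covariates enter the survival model z-scored (raw values are
retained with provenance flags), since the source analysis reports one
hazard ratio per covariate without stating units.

## Geometry

District polygons are read from GeoJSON (no shapefile reader is bundled;
GeoJSON round-trips losslessly as text). Geographic coordinates are
reprojected per region with a local sinusoidal projection — equal-area,
with sub-1% distance error at regional scales — because the correlation
range is interpreted in metres. The projection choice is a package
decision recorded here, not an attribute of the source analysis.
Multi-part districts use the area-weighted centroid of all parts; rings
are repaired cheaply (duplicate vertices, closure) and rejected with a
report if the outer ring still self-intersects or has zero area.
Patients are joined to districts through a normalised town lookup
(trim, case-fold, collapse whitespace); unmapped towns get an
`"unassigned"` sentinel, are counted, and are excluded from fitting.

## The synthetic world

Real registry data are access-restricted, so every stage is exercised
on synthetic cohorts whose defaults state the emulated world: 4412
patients over 144 square-grid districts split 87 + 57 between two
disjoint regions, 30 km cells (districts tens of kilometres across),
categorical covariates with explicit missing levels drawn completely at
random, administrative censoring at 2192 days (a six-year study
window), frailty field with $\sigma^2 = 0.25$ and $\phi = 50$ km, and
survival times drawn from the hazard model by inverse-transform
sampling (closed-form for exponential/Weibull, root-finding for the
B-spline). Three to six pseudo-towns per district exercise the
town-to-district join; a masked fraction of the socioeconomic index
exercises kriging.

What a green test does *not* establish: real registries have
informative missingness (simulated missingness is MCAR), non-square
districts with irregular adjacency, population-driven patient
clustering beyond the mild gradient simulated here, and a mixture of
administrative censoring and loss to follow-up (only the former is
simulated).

## Numerical choices

* Cholesky failures of the frailty covariance escalate a diagonal
  jitter ($10^{-10}\sigma^2$ upward); the magnitude used is recorded.
* B-spline $H_0$: adaptive quadrature (rel. tol $10^{-10}$) in the R
  interface; inside the sampler a 401-point trapezoid grid with linear
  interpolation (relative error $\sim10^{-6}$). Beyond the last knot the
  hazard is extended as a constant.
* Kriging variances are clamped at zero against round-off; weights are
  asserted to sum to 1 within $10^{-8}$ in tests.
* Equal-tailed 2.5/97.5% quantiles and medians summarise posteriors,
  matching the "median HR (95% CRI)" reporting convention; a credible
  interval excluding 1 sets the significance flag.
* Exceedance thresholds default to {1.1, 1.25, 1.5} (the union used for
  the two regions' published maps); probability bins break at 0.25,
  0.5, 0.75, following the reporting language, and both are
  configurable because the published captions disagree on one figure's
  thresholds.

## Known limitations

* $\phi$ is weakly identified; its posterior inherits real prior
  sensitivity. Recovery within a factor of 3 at moderate $m$ is the
  realistic expectation.
* WAIC comparisons at small effective sample sizes are noisy; the
  model-selection check is framed as a majority over replicates.
* The kernel density estimate has no edge correction by default, so
  boundary districts are biased low relative to interior ones.
* Cause-specific mortality, time-varying covariates and semi-parametric
  (Cox) baselines are out of scope.
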