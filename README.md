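# spfrail

Spatial survival analysis for district-level disease registries:
parametric proportional-hazards models with **log-Gaussian spatial
frailties**, Bayesian MCMC inference, WAIC baseline-family comparison,
ordinary-kriging imputation of area covariates, and covariate-adjusted
**exceedance-probability risk maps**.

## Who it is for

Epidemiologists and biostatisticians modelling how patient survival
(e.g. cancer registry cohorts) varies across administrative districts
after adjusting for individual covariates — and mapping the residual
spatial risk. Registry data of this kind are typically access-restricted,
so the package ships a synthetic-cohort generator with the same
statistical structure, making every stage testable end to end.

## The model

For patient *i* with follow-up time *t<sub>i</sub>* (days), event
indicator *δ<sub>i</sub>* (1 = dead, 0 = censored at end of study),
covariates *x<sub>i</sub>* and district *d(i)*:

```
h(t_i) = h0(t_i; ω) · exp( x_i'β + Y_d(i) )
Y ~ N( -σ²/2 · 1,  σ² · exp(-d_jk / Ø) )
```

* `h0` — exponential, Weibull, or cubic B-spline on the log hazard;
  families compared by WAIC.
* `β` — log hazard ratios; reported as median HR with 95% equal-tailed
  credible intervals.
* `Y` — district log-frailties with exponential correlation on centroid
  distances *d<sub>jk</sub>* (metres): correlation `e⁻¹` at distance `Ø`.
  The prior mean `-σ²/2` gives the multiplicative frailty `exp(Y)` unit
  prior mean.
* Risk maps show `P[exp(Y_j) > c]` — the posterior probability that a
  district's covariate-adjusted relative risk exceeds a threshold *c*
  (defaults 1.1, 1.25, 1.5).

Inference is blockwise adaptive random-walk Metropolis with a whitened
(Cholesky-decorrelated) frailty update, a centred covariance-parameter
update, and a level-transfer move along the baseline/frailty ridge; see
`vignettes/spatial-survival-methods.Rmd` for the design rationale.

## Worked example

```r
library(spfrail)

# a synthetic registry cohort: 1500 patients, 36 districts (30 km cells),
# Weibull baseline, frailty field with sigma2 = 0.25, range 100 km
spec <- cohort_spec(n_patients = 1500, n_west = 36, n_east = 1, cell = 30000,
                    covariates = list(
                      age = list(type = "numeric", mean = 62, sd = 13),
                      stage = list(type = "factor",
                                   levels = c("Early", "Late", "Missing"),
                                   prob = c(0.45, 0.4, 0.15))),
                    beta = c("age" = 0.15, "stage:Late" = 0.7),
                    baseline = baseline_weibull(1.5, 2e-5),
                    sigma2 = 0.25, phi = 1e5, censor_time = 2192, seed = 2024)
cohort <- generate_cohort(spec)

region <- cohort_region_dataset(cohort, "west", covariates = c("age", "stage"))
chain <- run_mcmc(region$data, ph_model_spec("weibull", region$D),
                  settings = mcmc_settings(20000, 6000, 14, seed = 1))
print(chain)
#> spfrail_chain: 1000 retained draws, weibull baseline, 36 districts
#> acceptance rates: beta=0.228  omega=0.251  frailty= 0.2  eta=0.236  level=0.412

hazard_ratio_table(chain)
#>       covariate  n hr_median hr_lower hr_upper significant
#> 1           age NA     1.181    1.118     1.24        TRUE
#> 2    stage:Late NA     2.065    1.810     2.30        TRUE
#> 3 stage:Missing NA     0.912    0.767     1.08       FALSE
```

The table mirrors the registry-style reporting: per non-reference level,
the posterior median hazard ratio with its 95% credible interval and a
significance flag when the interval excludes 1. Here the truth was
HR = e^0.15 ≈ 1.16 per sd of age and e^0.7 ≈ 2.01 for late stage — both
recovered within their intervals, with the null `Missing` effect
correctly not flagged.

```r
compute_waic(chain)
#> WAIC 20320.70  (lppd -10132.55, p_waic 27.80, 1000 draws)

correlation_curve(chain, c(0, 50000, 100000))
#>       d median lower upper
#> 1 0e+00  1.000 1.000 1.000
#> 2 5e+04  0.855 0.516 0.975
#> 3 1e+05  0.730 0.266 0.951

es <- exceedance_probability(chain, thresholds = c(1.1, 1.25))
head(es[, 1:3], 4)
#>   district_id p_exc_1.1 mcse_1.1
#> 1        W001      0.58    0.016
#> 2        W002      0.57    0.016
#> 3        W003      0.73    0.014
#> 4        W004      0.52    0.016
export_risk_map(es, region$map, "risk_maps")   # GeoJSON + PNG choropleths
```

The correlation curve summarises `exp(-d/Ø)` over posterior draws of `Ø`
(correlation still ~0.73 at 100 km here — consistent with the simulated
100 km range). The exceedance surface gives, per district, the
posterior probability that its adjusted relative risk exceeds each
threshold, with Monte-Carlo standard errors; districts W001–W004 were
simulated with genuinely elevated frailties (true Y ≈ 0.6–0.9), and all
show elevated `P[exp(Y) > 1.1]`.

Real data enter through the same interfaces: `load_district_map()`
(GeoJSON), `town_lookup()`/`assign_district()` for the registry's
free-text town field, `build_area_covariates()` for a partially observed
socioeconomic index (kriged at missing districts) and hospital density,
and `survival_dataset()`/`build_design_matrix()` for the patient table.

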