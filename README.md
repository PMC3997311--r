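# camtel

Camera traps and radio telemetry both measure where animals spend their
time, and density-estimation methods increasingly combine the two — on the
untested assumption that they carry consistent information. `camtel`
implements an explicit consistency check for marked animals: home-range
utilization distributions (UDs) are estimated from telemetry, cameras are
classified as *available* to each animal, and camera detections are
modelled as a function of telemetry-based space use. If the two data types
agree, detection hazard should be **proportional to the utilization
density** at the camera.

The package is aimed at quantitative wildlife ecologists who have (or want
to simulate) simultaneous telemetry and camera-trap data for collared
animals.

## The model

For animal–camera observation *i*, the linear predictor is the log capture
rate

    eta_i = beta_Sex(i) + beta_UD * log(UD_i)    (+ other terms)

so the capture rate is `lambda_i = exp(beta_Sex) * UD_i^beta_UD` and, over
an exposure of `T` days, the probability of at least one detection is

    pi_i = 1 - exp(-lambda_i * T)

which is exactly a binomial GLM with a complementary log-log link. If
cameras measure space use consistently with telemetry, `beta_UD = 1`; the
*simple model* `Sex + offset(log(UD))` forces this, while free-exponent
models estimate `beta_UD` to test it. Candidate sets additionally contain
isopleth-percentile and core/non-core effects (do animals find cameras in
their core range out of proportion to time spent there?), compared by AICc
(binomial GLMs), QAICc (quasi-Poisson photo counts, dispersion from the
saturated model) or AIC (random-intercept GLMMs per animal, camera, or
animal/camera), with Akaike weights and Nakagawa–Schielzeth conditional
R². A second, home-range-free *proximity analysis* predicts detection from
the number of telemetry relocations within 250/500 m of each camera.

Home ranges are fixed-kernel UDs with the bivariate-normal reference
bandwidth `h_ref = sqrt((s_x^2 + s_y^2)/2) * n^(-1/6)`, scaled by the
smallest multiplier in {0.6, …, 0.9} whose 90%/95% isopleths stay cohesive
and close to the data extent (reference bandwidth as fallback). Analyses
use the home range up to the 90% isopleth.

A Gaussian-mixture movement simulator generates populations with
sex-dimorphic ranges (male areas ≈ 3× female), telemetry with aerial
positional error, jittered 1-km camera grids with staggered deployment
windows, and detections drawn from the rate model above — so every claim
can be validated by parameter recovery.

## Worked example

```r
library(camtel)

cfg <- sim_config(n_females = 10, n_males = 5,
                  extent = c(10000, 6000), seed = 14)
tab <- simulate_encounter_data(cfg, with_isopleth = TRUE, seed = 14)
res <- run_homerange_analysis(tab)
res$binary$table
```

```
Model selection (AICc)
                          model K     ic delta weight cum_weight r2c
            Sex + offset(logUD) 2 502.96  0.00   0.26       0.26  NA
                    Sex + logUD 3 503.72  0.76   0.18       0.43  NA
 Sex + Isopleth + offset(logUD) 3 503.83  0.87   0.17       0.60  NA
     Sex + Core + offset(logUD) 3 504.70  1.74   0.11       0.70  NA
               Isopleth + logUD 3 505.15  2.19   0.09       0.79  NA
 Sex * Isopleth + offset(logUD) 4 505.47  2.51   0.07       0.86  NA
                    Sex * logUD 4 505.73  2.77   0.06       0.93  NA
     Sex * Core + offset(logUD) 4 506.05  3.10   0.05       0.98  NA
                 Sex + Isopleth 3 510.13  7.17   0.01       0.99  NA
              1 + offset(logUD) 1 510.18  7.23   0.01       1.00  NA
                 Sex * Isopleth 4 511.18  8.22   0.00       1.00  NA
```

On data generated from the proportional model, the simple model
`Sex + offset(logUD)` is ranked first and the models without `log(UD)`
(`Sex + Isopleth`, `Sex * Isopleth`) trail by 7–8 AICc units: utilization
density, not isopleth position, predicts detections. The recovery loop
quantifies estimator calibration:

```r
run_recovery_experiment(cfg, n_reps = 20, ud_source = "true", seed = 14)
```

```
<recovery_report> 20 replicates (0 failed), UD source: true, mean rows 463
 parameter truth mean_estimate  bias  rmse coverage
   beta_ud   1.0         1.030 0.030 0.181     0.90
    beta_f  12.5        12.987 0.487 3.063     0.90
  sex_diff   0.7         0.747 0.047 0.245     0.95
top model frequencies:
tops
  free offset
   0.2    0.8
```

The free-exponent estimate of `beta_UD` is unbiased (mean 1.03 over 20
replicates), its 95% Wald intervals cover the truth at near-nominal rates,
and the proportional offset model wins the AICc comparison in 80% of
replicates. With `ud_source = "kernel"` the UD covariate is replaced by
the fixed-kernel estimate from simulated telemetry, measuring the
attenuation home-range estimation error induces.

The full pipeline (telemetry → kernel home ranges → availability →
encounter table → model suites) runs through `simulate_study()`,
`estimate_homeranges()`, `build_encounter_table()`,
`run_proximity_analysis()` and `run_homerange_analysis()`; see the
methods vignette (`vignettes/camtel-methods.Rmd`) for the modelling
details and design choices.

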