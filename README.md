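# gsempa

Generalized structural equation modelling of latent physical-activity
dimensions and obesity, for epidemiologists analysing time-use survey data.

Surveys record *how many minutes per week* people spend on specific
activities — screen time on a computer or smartphone, television, video
games; travel by motor vehicle, bicycle, or on foot — but the constructs of
interest ("screens use", "active transportation") are latent. `gsempa`
estimates, by joint maximum likelihood, a model with three blocks:

* **Measurement**: each weekly time *t<sub>ij</sub>* is Weibull with shape
  *k<sub>j</sub>* and scale
  *exp(κ<sub>j</sub> + λ<sub>j</sub> L<sub>id</sub>)* — an
  accelerated-failure-time measurement model whose right-skew matches
  weekly activity times. One reference indicator per latent has λ fixed at
  1, so loadings are ratios to the reference.
* **Structural**: the latent vector is bivariate normal with means
  Γs<sub>i</sub> (paths from leisure-time physical activity) and free
  covariance Ψ.
* **Disease**: obesity (BMI ≥ 30) is Bernoulli with log link,
  log π = α + β₁L₁ + β₂L₂ + x′β — the "modified Poisson" formulation whose
  exponentiated coefficients are prevalence ratios (PRs), with a robust
  sandwich variance.

The marginal likelihood integrates the latents out by adaptive
Gauss–Hermite quadrature with analytic scores; BFGS plus a
Levenberg-regularised Newton polish maximizes it. Around the estimator the
package provides the full survey workflow: a synthetic data generator
emulating the national nutrition survey structure the model was designed
for, Table-1-style descriptives (weighted prevalence, chi-square,
Mann–Whitney), factorability diagnostics (distribution goodness of fit,
KMO, Bartlett sphericity, principal-axis loadings), direct and indirect
(product-of-paths) effect tables, empirical-Bayes adherence scores with
tertiles, department-level prevalence summaries for mapping, and a
single-config reproducible pipeline.

## Worked example

Simulate a survey-like dataset under the default study conditions (obesity
prevalence calibrated to 19.1%, loadings 1/3.9/−20.3 and 1/−5.4/0.8) and
fit the joint model:

```r
library(gsempa)

cfg  <- synthetic_config(n_persons = 5000)
dat  <- generate_dataset(cfg, seed = 42)
spec <- gsem_spec(
  latents = list(screens   = c("computer_smartphone", "tv", "video_games"),
                 transport = c("motor_vehicle", "cycling", "walking")),
  disease    = obesity ~ sex + age + ethnicity + schooling + wealth_quartile +
                         energy_kcal + leisure_pa,
  structural = ~ leisure_pa)
fit <- fit_gsem(spec, dat)
print(fit)
effect_table(fit)[c(1:3, 13:16), ]
```

```
Generalized structural equation model (Weibull indicators, log-link disease model)
  5000 persons, 35 free parameters, 13-node adaptive quadrature per dimension
  logLik -166274.35 | AIC 332618.7 | BIC 332846.8 | converged
  latent prevalence ratios: screens 1.743, transport 0.810

                      term       coef        se         PR    ci_low    ci_high   p_value   effect
1              (Intercept) -2.4360566 0.1736261  0.0875052  0.062265  0.1229773 1.015e-44   direct
2                sexfemale  0.5353822 0.0607732  1.7081010  1.516294  1.9241714 1.257e-18   direct
3                      age  0.0156354 0.0026277  1.0157582  1.010540  1.0210031 2.677e-09   direct
13               L.screens  0.5553239 0.3428585  1.7425053  0.889882  3.4120534 1.053e-01   direct
14             L.transport -0.2104668 0.0621719  0.8102059  0.717257  0.9152006 7.112e-04   direct
15   leisure_pa -> screens -0.0004904 0.0003017 -0.0004904 -0.001082  0.0001009 1.040e-01 indirect
16 leisure_pa -> transport -0.0008896 0.0002629 -0.0008896 -0.001405 -0.0003742 7.168e-04 indirect
```

The latent *Active transportation* is protective (PR ≈ 0.81 per unit of the
continuous index, 95% CI 0.72–0.92), female sex and age raise prevalence,
*Screens use* is not significant, and the indirect effect of leisure-time
activity through active transportation is a small negative product of
coefficients (≈ −0.0009, delta-method CI excluding zero), reported
unexponentiated. Adherence scores and department summaries follow with

```r
scores <- eb_scores(fit)
department_summary(dat, scores, weights = "expansion_factor")
```

or run everything (simulate → describe → diagnose → fit → effects → score →
map-summaries) from one config:

```r
run_pipeline(system.file("extdata", "example_pipeline.yaml", package = "gsempa"),
             outdir = "results/example")
```

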