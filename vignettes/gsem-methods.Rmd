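---
title: "Modelling latent physical-activity dimensions and obesity with gsempa"
author: "gsempa authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling latent physical-activity dimensions and obesity with gsempa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`gsempa` estimates a generalized structural equation model (GSEM) designed for
survey data in which physical-activity behaviour is observed only through
weekly minutes spent on specific activities. Two latent dimensions are
posited: *Screens use*, measured by computer/smartphone, television and
video-game minutes per week, and *Active transportation*, measured by motor
vehicle, cycling and walking minutes per week. The joint model has three
blocks.

**Measurement models.** Each indicator time \(t_{ij}\) is Weibull on the
accelerated-failure-time scale,
\[
t_{ij} \mid L_{id} \sim \mathrm{Weibull}\!\big(k_j,\;
b_{ij} = \exp(\kappa_j + \lambda_j L_{id})\big),
\]
with shape \(k_j > 0\) free per indicator, intercept \(\kappa_j\) on the log
minutes/week scale, and loading \(\lambda_j\). One reference indicator per
latent has its loading fixed at 1 (computer/smartphone and motor vehicle by
convention), which makes the remaining loadings interpretable as ratios to
the reference and, together with a free latent variance, identifies the
scale (the Stata-style convention). The Weibull family fits the strong right
skew of weekly activity times; the conditional median is
\(b_{ij}(\log 2)^{1/k_j}\).

**Structural block.** The latent vector is bivariate normal,
\(L_i \sim N(\Gamma s_i, \Psi)\), with \(s_i\) the structural covariates
(leisure-time physical activity, minutes/week, in the default analysis) and
\(\Psi\) a free SPD covariance (log-Cholesky parameterised internally). No
latent intercept is used: location is carried by the \(\kappa_j\), so the
paths \(\gamma_d\) are identified by covariation only.

**Disease model.** Obesity (BMI \(\ge\) 30) follows a Bernoulli with log
link,
\[
\log \pi_i = \alpha + \beta_1 L_{i1} + \beta_2 L_{i2} + x_i^\top\beta,
\]
the "modified Poisson" formulation: exponentiated coefficients are
prevalence ratios (PRs), and inference uses a robust sandwich variance. We
use a genuine Bernoulli likelihood (required for a proper joint density over
latents) rather than a Poisson pseudo-likelihood; the robust variance
\(A^{-1} B A^{-1}\), with \(A\) the observed information and
\(B = \sum_i w_i^2 s_i s_i^\top\) from per-person scores, reproduces the
modified-Poisson inferential behaviour. Because the log link does not
constrain \(\pi < 1\), the linear predictor is softly capped just below 0
(a smooth soft-minimum with sharpness 0.01 and offset `1e-8`); in sensible
configurations the capped region carries negligible posterior mass, and the
synthetic generator reports its capped fraction (kept below 0.1% in the
default design).

Indirect effects of a structural covariate through latent \(d\) are the
path products \(\gamma_d \beta_d\), reported on the coefficient (log) scale
with first-order delta-method standard errors
\(\beta^2 \mathrm{var}(\hat\gamma) + \gamma^2 \mathrm{var}(\hat\beta) +
2\gamma\beta\,\mathrm{cov}(\hat\gamma,\hat\beta)\). They are deliberately not
exponentiated: a product of a per-minute path and a log-PR is not itself a
log prevalence ratio, and published tables of this design print the raw
product (values like −0.0006).

## Estimation

The marginal likelihood integrates the product of the six Weibull densities,
the Bernoulli term and the bivariate normal prior over \(L_i\). We use
*adaptive* Gauss–Hermite quadrature: per person, a damped Newton search
finds the posterior mode of \(L_i\) (the integrand is log-concave in
\(L\)), the local curvature rescales the Gauss–Hermite grid, and the nodes
are re-centred there. Maximization is BFGS with analytic gradients obtained
from the Fisher identity — the score of the integrated likelihood is the
posterior expectation of the complete-data score, evaluated on the same
grid. The small dependence of the adapted nodes on the parameters is not
differentiated; tests verify the analytic gradient against central finite
differences to a few parts per thousand.

**Node counts.** The Weibull kernel in \(L\) is a double-exponential wall on
one side, so posteriors under strong loadings (e.g. a loading of −20 on a
latent with SD 0.1) are noticeably skewed and need more nodes than the
customary handful. Convergence diagnostics on the default design show the
log-likelihood stabilises (relative changes below \(10^{-6}\)) by roughly 17
nodes in one dimension and 13 per dimension in two; the defaults are 41 for
one latent (where nodes are cheap, and where the extra margin also removes
the residual bias of the fixed-node gradient near the optimum) and 13 per
dimension for two latents, and `quad` is exposed everywhere.

**Start values** are deterministic: marginal Weibull fits (via
`survival::survreg`) give \(\kappa_j, k_j\); the covariance of log times
gives method-of-moments loadings and latent SD through
\(\sigma^2 = \mathrm{cov}(r,a)\,\mathrm{cov}(r,b)/\mathrm{cov}(a,b)\) around
the reference \(r\) and \(\lambda_j = \mathrm{cov}(\log t_j, \log t_r)/\sigma^2\)
(falling back to \(0.1 \times\) the correlation sign when the triple is
degenerate); a latent-free Poisson-family log-link fit seeds the disease
coefficients; paths and the latent correlation start at zero. For the full
joint model, each latent's measurement sub-model is pre-fitted alone and its
estimates seed the joint start (`prefit` control). Moment-based loading
starts matter in practice: quasi-Newton from a generic small start is slow
and fragile when true loadings are an order of magnitude larger.

Because the loading/latent-SD ridge of a strong-loading measurement model
is a curved valley on which BFGS creeps, the optimizer finishes with
safeguarded Newton "polish" steps whose curvature matrix is the outer
product of per-person scores (BHHH — equal to the information at the
optimum by the information identity), with a Levenberg-style ridge
regularisation and line search.

Latent-free specifications (no latents declared) reduce to log-link
Bernoulli regression; after BFGS these are polished by safeguarded Newton
steps so the optimum matches an IRLS GLM fit to at least six significant
figures. Non-convergence is always flagged (`converged = FALSE`), never
silently accepted, and the pipeline treats it as a stage failure.

**Weights.** Survey expansion factors, when declared, multiply the
per-person log-likelihood contributions; the sandwich \(B\) uses squared
weights. Duplicating every record at half weight reproduces the unweighted
fit exactly, which is the contract the tests enforce. Replication of a real
multistage design (clustering, stratification) is out of scope.

## Empirical-Bayes scores and downstream summaries

Per-person adherence scores are posterior means of each latent given the
person's indicators, covariates and (by default) outcome, computed on the
same adaptive grid; `condition = "indicators"` restricts conditioning to the
measurement block. Tertiles of each score distribution (type-7 quantiles,
left-closed intervals) define low/moderate/high adherence. Department-level
summaries combine survey-weighted prevalence (logit-scale Wald intervals
with Kish effective sample size) with unweighted median adherence, binned
into type-7 quartiles — attribute tables ready to join to map geometries;
rendering is left to GIS tools.

Pre-modelling diagnostics follow the conventional workflow: per-indicator
maximum-likelihood fits of Weibull/gamma/lognormal/exponential ranked by
AIC with Kolmogorov–Smirnov statistics; KMO sampling adequacy and
Bartlett's sphericity on the correlation matrix of log times (the scale on
which the measurement model is linear; the source analysis does not state
its scale, so Spearman on raw times is available as an option); and
principal-axis factoring with varimax rotation for exploratory loadings
(the extraction method is likewise not stated in the source analysis;
principal axis is the common default and is exposed in code).

## The synthetic generator

`synthetic_config()` encodes the study conditions the package is exercised
under: n = 9,658 by default; 56.2% female; age truncated-normal 38.5 (SD
13.1) on 18–64; ethnicity 90.9/7.1/2.0% (other/Afro-descendant/Indigenous);
schooling 15.9/75.3/8.8%; wealth quartiles 29.5/23.7/24.4/22.4%; energy
intake lognormal with median 2,000 kcal/day; leisure-time activity a 45%
point mass at zero plus a gamma with mean 220 min/week. Measurement truth:
loadings (1, 3.9, −20.3) on Screens use with SD 0.1 and intercepts
log(45)/log(420)/log(30); loadings (1, −5.4, 0.8) on Active transportation
with SD 0.5 and intercepts log(140)/log(20)/log(70); all shapes 1.3; latent
residual correlation 0.2 (a covariance is posited between the dimensions
but its value is not published; 0.2 is a mild positive default). Structural
paths per minute/week of leisure activity are 0.00424 into Active
transportation and −0.00098 into Screens use — the latter back-calculated
so that the product with the screens log-PR matches the published indirect
effect (−0.00017). Disease-model truth uses the published PRs (female 1.71,
age 1.02/year, Afro-descendant 1.36, Indigenous 1.09, wealth Q2–Q4
1.23/1.13/1.04, energy 1.00, leisure activity 0.9996/min, screens 1.19,
transport 0.86 per latent unit); schooling coefficients default to zero
since no PRs are published for them. The intercept is calibrated by
root-finding so the marginal prevalence of `min(exp(eta), 1)` hits 19.1%,
with the capped fraction reported (zero to <0.1% in the default design).

The generator emulates the *statistical structure* the analysis assumes —
independent persons, exact Weibull measurement, exact log-link disease
model, self-weighted sampling (expansion factors default to 1, with an
optional gamma weight model), multinomial department assignment with
optional per-department prevalence shifts. It does not emulate multistage
sampling, questionnaire measurement error, item non-response, or real
spatial correlation. Passing recovery tests therefore demonstrates the
estimator is correct under its own assumptions, not that those assumptions
hold in any real survey. Note that marginal indicator medians sit below
`exp(kappa)` because of the shape factor \((\log 2)^{1/k}\) and latent
variation; the intercepts are kept at the published medians' logs because
the recovery benchmarks pin them there.

BMI is populated as descriptive furniture consistent with the Bernoulli
obesity draw (the analysis models obesity occurrence, not BMI), and the
`obesity == (bmi >= 30)` invariant holds for every record. Indicator times
are strictly positive by construction; for real data ingestion the
documented convention is a +1 minute shift before log/Weibull modelling.

## Numerical choices and degenerate inputs

* Quadrature needs at least 3 nodes; mode search uses damped Newton with
  step halving, capped steps, and a decrement tolerance of \(10^{-11}\).
* Likelihood evaluations reject absurd parameter regions (|log shape| > 25,
  |θ| > 10^6) so line searches cannot overflow the Weibull terms; the
  Weibull exponent is additionally capped at 50 inside node evaluations.
* BFGS uses `parscale` set from covariate scales so coefficients of
  kcal/day- or minutes/week-scaled covariates do not stall the search;
  convergence additionally requires the largest scaled gradient below
  `gtol * max(1, |loglik|)`.
* Tertiles and quartile bins are type-7 quantiles with left-closed
  intervals; ties share the upper interval; fully degenerate distributions
  yield the lowest category with a warning.
* `weighted_prevalence` returns a degenerate interval when the estimate is
  0 or 1; chi-square tests refuse zero margins; KMO refuses identity and
  singular correlation matrices.

## Problem sizes used by the test suite

Unit tests run on 100–5,000 simulated persons. The recovery benchmarks use
n = 20,000 (one fit per measurement model, one joint fit), the sandwich
coverage check uses 200 replicates of n = 2,000 latent-free fits, and the
oracle equivalences use n = 50 with 100,000 Monte-Carlo draws per person,
a 20,001-point grid for the empirical-Bayes posterior, and an IRLS GLM for
the latent-free fit. These sizes were chosen so each simulation's Monte
Carlo error is small relative to the tolerance it is tested against.

## Known limitations

* Exactly one or two latent dimensions; Weibull indicators and a Bernoulli
  log-link outcome only — the families the design calls for.
* Complete cases only; records with missing indicators are rejected.
* Descriptive chi-square/Mann-Whitney tests are unweighted
  (no Rao–Scott design correction), matching the descriptive-table use.
* The robust variance treats persons as independent; no cluster sandwich.
* Indirect effects are path products, not counterfactual mediation
  estimands.
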