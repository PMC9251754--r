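# rwenma

Predicting real-world treatment outcomes by combining individual patient
data (IPD) from randomized trials and disease registries.

## What problem this solves

Randomized controlled trials (RCTs) give unconfounded estimates of relative
treatment effects, but in selected populations under controlled conditions;
registries describe routine care, but treatment choice there depends on the
patients themselves.  The difference between what trials promise and what
routine care delivers is the *efficacy–effectiveness gap*.  When a
clinician wants a predicted outcome for one patient under each available
treatment *as given in routine care*, both sources are needed.

`rwenma` implements a two-stage Bayesian IPD network meta-analysis for a
continuous outcome.  Each study — trial or registry — is analysed
separately with the regression

    y_ij ~ Normal( a_j + b_j' x_ij + c_{j,tA}' x_ij + d_{j,tA} ,  sigma_j^2 )

and the study-level estimates are pooled into the prediction model

    y_hat(x, t) = alpha + beta' x + gamma_tA' x + delta_tA ,

where `A` is the reference treatment, `beta` holds prognostic effects,
`gamma_tA` effect modifiers (treatment–covariate interactions, optionally
shrunk with a Laplace / Bayesian-LASSO prior), and `delta_tA` the relative
effect of `t` versus `A`.  Seven assembly strategies are provided, from
"use one registry only" (approach I), through design-naive pooling of all
studies without or with shrinkage (IIa/IIb) and re-calibration of the
intercept and main effects to a target registry (IIc), to design-adjusted
pooling that inflates registry variances on relative effects by `1/w`
(IIIa/IIIb) and a no-effect-modifier simplification (IV).  Model evaluation
— MSE/bias, R², calibration of predicted outcomes and of predicted
*treatment benefit*, bootstrap optimism correction, and leave-one-registry-
out cross-validation — is built in, along with chained-equations
predictive-mean-matching imputation and a synthetic multi-study IPD
generator with tunable confounding and efficacy–effectiveness gap.

It is aimed at biostatisticians doing evidence synthesis and prediction
modelling across trials and real-world data sources.

## Worked example

Simulate a rheumatoid-arthritis-like network — three two-arm RCTs, two
three-arm registries, 5,500 patients, nine covariates, a DAS28-like 0–10
outcome, registry treatment assignment depending on covariates, registry
effects attenuated by +0.3 — mask 5% of covariate cells, and fit the
design-naive pooled model with shrinkage (approach IIb):

```r
library(rwenma)

ipd <- simulate_ipd(sim_config(), seed = 42)
ipd <- inject_missingness(ipd, 0.05, "mcar", seed = 43)
ipd
#> IPD set: 5 studies, 5500 patients
#>   rct1         RCT  n=500   arms: dmards, rtx
#>   rct2         RCT  n=1200  arms: dmards, tcz
#>   rct3         RCT  n=800   arms: dmards, tcz
#>   reg1         NRS  n=2000  arms: dmards, rtx, tcz
#>   reg2         NRS  n=1000  arms: dmards, rtx, tcz
#> covariates: x1, x2, x3, x4, x5, x6, x7, x8, x9

fit <- rwe_fit(ipd, approach = "IIb", reference = "dmards", m = 5,
               mcmc_study = mcmc_settings(profile = "test"),
               mcmc_pool = mcmc_settings(chains = 3, iter = 5000,
                                         burnin = 1000),
               seed = 44)
summary(fit)$table[c("alpha", "beta.x1", "gamma.x1:rtx",
                     "delta.rtx", "delta.tcz"), ]
#>                mean    sd  lower  upper
#> alpha         3.840 0.041  3.759  3.920
#> beta.x1      -0.260 0.022 -0.304 -0.217
#> gamma.x1:rtx -0.037 0.033 -0.101  0.027
#> delta.rtx    -0.775 0.055 -0.882 -0.666
#> delta.tcz    -0.972 0.048 -1.066 -0.879
```

`alpha` is the expected outcome under the reference at covariate value
zero, pooled across studies; `delta.rtx` and `delta.tcz` say that, at equal
covariates, the two biologic strategies lower the six-month disease score
by about 0.78 and 0.97 points versus conventional treatment (the generating
values, after the simulated registry attenuation, bracket these); the
near-zero shrunk `gamma` terms correctly reflect that this simulation has
no effect modification.  Predictions for a new patient propagate the full
posterior:

```r
patient <- data.frame(x1 = 0.8, x2 = 0.2, x3 = -0.4, x4 = 1.1, x5 = 0,
                      x6 = 0.3, x7 = 1, x8 = 0, x9 = 1)
predict(fit, patient)
#>   patient treatment      fit      lwr      upr
#> 1       1    dmards 3.951814 3.843497 4.059828
#> 2       1       rtx 3.132136 3.000126 3.265857
#> 3       1       tcz 2.967311 2.858483 3.079009
predict(fit, patient, treatment = "tcz", type = "benefit")
#>   patient treatment comparator        fit       lwr        upr
#> 1       1       tcz     dmards -0.9845036 -1.103608 -0.8649841
```

So for this patient the model expects a six-month score near 3.95 if they
stay on conventional DMARDs and about 0.98 points lower on TCZ, with a 95%
credible interval for that benefit of roughly −1.10 to −0.86.

Model comparison uses `internal_validation()` (bootstrap
optimism-corrected, scored on each registry) and `internal_external_cv()`
(each registry left out in turn).  See the methods vignette
(`vignettes/methods.Rmd`) for the models, priors, and every design choice.

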