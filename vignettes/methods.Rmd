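---
title: "Predicting real-world outcomes from randomized and non-randomized IPD: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting real-world outcomes from randomized and non-randomized IPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Randomized trials estimate relative treatment effects under controlled
conditions; disease registries describe the patients and outcomes of routine
care.  When the goal is to tell an individual patient what outcome to expect
under each of several available treatments *in routine care*, neither source
suffices alone: trials are unconfounded but unrepresentative, registries are
representative but confounded.  `rwenma` implements a two-stage
individual-patient-data (IPD) network meta-analysis that combines both,
yielding a multivariable prediction model for a continuous outcome

$$ \hat y(x, t) \;=\; \alpha + \beta^\top x + \gamma_{tA}^\top x +
\delta_{tA}, $$

where $A$ is a reference treatment, $x$ a vector of baseline covariates,
$\beta$ the prognostic main effects, $\gamma_{tA}$ the effect modifiers
(treatment-covariate interactions) of treatment $t$ versus $A$, and
$\delta_{tA}$ the relative effect of $t$ versus $A$ at $x = 0$.  We fix
$\gamma_{AA} = 0$ and $\delta_{AA} = 0$.  The motivating setting is
rheumatoid arthritis — three drug strategies (conventional DMARDs, and two
biologic combinations), a 0–10 disease-activity score measured six months
after treatment start, and about nine baseline covariates — but the code is
agnostic to disease area.

## Two-stage estimation

**Stage one** (`fit_study()`) analyses each study separately with a Bayesian
linear regression

$$ y_{ij} \sim N(a_j + b_j^\top x_{ij} + c_{j,t_{ij}A}^\top x_{ij} +
d_{j,t_{ij}A},\; \sigma_j^2), $$

giving a posterior-mean vector $\hat\theta_j$ and covariance $\hat S_j$ per
study.  Multi-arm studies are fitted jointly (shared $a_j$, $b_j$,
$\sigma_j$), so $\hat S_j$ carries the between-contrast correlation.  A
study that lacks the global reference is parameterized against its largest
arm, and re-expressed against the global reference at stage two through the
consistency relations $\delta_{WA} = \delta_{WB} + \delta_{BA}$ (and the
analogous relations for $\gamma$, the intercept and the main effects),
which hold exactly in every posterior draw.

**Stage two** pools the $(\hat\theta_j, \hat S_j)$ with a multivariate
meta-analysis in which each study's likelihood is
$\hat\theta_j \sim N(M_j \phi, \hat S_j)$ for a selection/consistency
matrix $M_j$, so studies inform only the parameters they estimate.  Four
pooling models are available:

* `pool_common()` — all parameters common across studies (the default for
  sparse networks, where heterogeneity is barely identifiable);
* `pool_random_tau()` — study-specific relative effects around the pooled
  ones with one between-study standard deviation $\tau$ shared across
  contrasts;
* `pool_full_mv()` — a full (or diagonal) between-study covariance over the
  whole parameter vector, practical only when studies outnumber parameters;
* `pool_design_adjusted()` — the covariance of each non-randomized study's
  relative-effect block $(\hat c_j, \hat d_j)$ is inflated by $1/w$,
  $0 < w \le 1$, down-weighting confounded evidence on relative effects,
  while the intercept and main effects are pooled from the registries only
  (they describe the real-world population the model targets).  As
  specified, the two blocks enter as separate likelihood contributions; the
  cross-covariance between them is not used.

## The seven modelling approaches

`rwe_fit(ipd, approach = ...)` assembles the prediction model:

| approach | $(\alpha, \beta)$ from | $(\gamma, \delta)$ from | shrinkage |
|---|---|---|---|
| I    | a single registry           | the same registry        | yes |
| IIa  | all studies, design-naive   | all studies              | no  |
| IIb  | all studies, design-naive   | all studies              | yes |
| IIc  | the target registry         | all studies              | yes |
| IIIa | registries only             | design-adjusted pooling  | yes |
| IIIb | the target registry         | design-adjusted pooling  | yes |
| IV   | all studies, design-naive   | all studies, $\gamma \equiv 0$ | no |

The calibrated approaches (IIc, IIIb) exist because trial populations are
selected: the registry is usually the best source for the absolute level
(intercept, main effects), while the trials are the best source for
relative effects.

## Shrinkage of effect modifiers

Effect modifiers are the hardest parameters to estimate and the most
consequential for treatment choice, so approaches I/IIb/IIc/IIIa/IIIb place
a Laplace prior $\pi(\gamma_k \mid \lambda) = \tfrac\lambda2
e^{-\lambda|\gamma_k|}$ on each interaction coefficient (a Bayesian LASSO
when $\lambda$ gets a hyperprior; the default is $\lambda \sim
\text{Gamma}(0.1, 0.1)$, exposed in `prior_settings()`).  Only the
interactions are penalized — prognostic main effects are not.  Because a
common penalty is only meaningful on a common scale, continuous covariates
are standardized study-wise (sample SD; binary covariates are left alone,
so their penalization is not scale-equalized — a documented limitation of
the modelling scope) and the fitted coefficients are mapped back to the
natural scale *exactly* before pooling:

$$ a' = a - \sum_k b_k \mu_k / s_k, \quad b'_k = b_k / s_k, \quad
c'_{k} = c_{k}/s_k, \quad d' = d - \sum_k c_{k}\mu_k/s_k, $$

applied to every posterior draw (so the covariance transform is the exact
Jacobian congruence $S' = J S J^\top$, which preserves positive
semi-definiteness, and the linear predictor of any patient is identical on
both scales to machine precision).

In the sampler the Laplace prior is implemented through its
normal–scale-mixture representation ($c_k \sim N(0, s_k^2)$, $s_k^2 \sim
\text{Exp}(\lambda^2/2)$), which has the identical marginal density but
keeps every coefficient update conjugate; with a native double-exponential
prior the same fits are an order of magnitude slower.

## Computation

All models are fitted by MCMC with JAGS (`rjags`).  The Gaussian stage-one
likelihood is supplied through its exact sufficient-statistic
factorization: the least-squares estimate is $N(\theta, \sigma^2
(X^\top X)^{-1})$ and the residual sum of squares is $\sigma^2
\chi^2_{n-q}$, independent of it.  This is an algebraic identity, not an
approximation — the posterior is unchanged — and it makes the per-fit cost
independent of the study's sample size, which matters inside the bootstrap
and cross-validation loops.  Rank-deficient designs are an error; an arm
with fewer than `n_cov + 2` patients triggers a warning.

Default chain settings (`mcmc_settings()`): 3 chains of 10,000 iterations
(1,000 burn-in) for study fits and 3 × 200,000 (20,000 burn-in) for
pooling, with convergence monitored by the Gelman–Rubin statistic
(threshold 1.05; a warning by default, an error if requested).  The test
suite and the demonstration script use reduced profiles (3 × 2,000 study
fits, 3 × 5,000 pooling) — with the sufficient-statistic likelihood and
conjugate updates these already give Monte-Carlo errors far below the
tolerances being checked.

Prior defaults are deliberately vague and exposed in `prior_settings()`:
$N(0, 100^2)$ on regression coefficients, $U(0, 100)$ on standard
deviations.  These are conventional choices, not derived quantities.

## Missing covariates

`impute_study()` runs chained-equations predictive mean matching within
each study separately: each incomplete covariate is regressed on the other
covariates, treatment indicators, treatment–covariate interactions and the
outcome; a missing entry receives the observed value of one of the $k = 5$
nearest donors by predicted mean, over 10 chained cycles, giving $m$
completed data sets (default $m = 20$).  Outcomes are never imputed; rows
with missing outcomes are kept for the imputation model but excluded from
the regression likelihood.  Covariates missing for an entire study
(systematically missing) are rejected — multilevel imputation across
studies is out of scope.  The donor count and cycle count are assumptions
(the reference implementation's defaults), exposed as arguments.

Analyses are combined across imputations by fitting the Bayesian model to
each completed data set and *mixing the posterior draws* (concatenation),
rather than by Rubin's rules; the mixed draws then yield $\hat\theta_j$ and
$\hat S_j$.  Destandardization is applied per completed data set (each has
its own scaling) before mixing.  When a study has no missing cells the $m$
copies are identical and a single fit is used.

## The synthetic-data generator

Real multi-study IPD of this kind is essentially never public, so
`simulate_ipd()` is a first-class module, not a test fixture.  It generates
the structure the framework assumes: a connected treatment network (default:
three two-arm trials of roughly 500/1,200/800 patients and two three-arm
registries of roughly 2,000/1,000 — the scale of the motivating example);
correlated continuous and binary covariates; uniform randomization in
trials versus a multinomial-logit assignment in registries whose
coefficients tie treatment choice to covariates (confounding by
indication); study-level effects drawn around design-specific means with
between-study SD $\tau$; and an *efficacy–effectiveness gap* implemented as
two independent knobs — a registry-specific intercept (default 3.5 versus
4.0 in trials, on the 0–10 outcome scale) and an additive attenuation of
the registry relative effects ($\delta^{NRS} = \delta^{RCT} + \Delta$,
default $\Delta = +0.3$ against trial effects of roughly $-0.8$ to $-1.1$).
Residual SD defaults to 1.2, in line with the mean-squared errors around
1.4–1.6 such models achieve on real registry data.  Outcomes can optionally
be clamped to $[0, 10]$; clamping is off in every recovery test because it
breaks the linear-model truth.  The generator returns the full truth record
(including realized study-level effects) for parameter-recovery checks.

What the generator does *not* emulate: real covariate dependence structures
beyond an exchangeable correlation, non-linear outcome surfaces, informative
missingness in outcomes, and measurement error.  Tests passing on these
simulations therefore certify the estimation machinery, not the clinical
adequacy of a linear model on any particular data set.

## Model evaluation

Because the goal is real-world prediction, metrics are always computed on
registry patients.  `mse_bias()`, `r_squared()`, `calibration_outcome()`
(observed outcome regressed on predicted outcome, shared intercept, one
slope per treatment) and `calibration_benefit()` implement the performance
battery; calibration for *benefit* regresses the observed outcome on the
predicted outcome under the reference plus the predicted
treatment-minus-reference differences of the received arm — a model can
predict outcomes well and benefits poorly, and this line is what detects
it.  All calibration lines are ordinary least squares.

`internal_validation()` trains every approach on all data, scores it on
each registry (the target-anchored approaches I/IIc/IIIb use the evaluated
registry as their target), and corrects for optimism with a bootstrap that
resamples patients within study and arm, preserving the multi-study,
multi-arm design.  Optimism is reported as (performance of the bootstrap
model on its bootstrap data) minus (its performance on the original data),
and `corrected = apparent - optimism` uniformly; note the sign — for an
error metric such as MSE, over-optimism appears as a *negative* optimism
value, and the correction inflates the apparent MSE.  Bootstrap refits may
use reduced chains via `boot_mcmc` (recorded in the report): hundreds of
full-length refits buy no additional accuracy for a mean-difference
estimate.

`internal_external_cv()` estimates transportability: each registry is left
out in turn, the models are trained on the rest, and the left-out registry
is scored.  Approach I cannot use the left-out registry, so its fold model
is trained on the remaining registries (pooled when more than one remains);
IIc and IIIb estimate their intercept/main-effect block from the remaining
registries only, never from trials.  Folds whose training network loses a
treatment or its connectivity fail loudly rather than silently shrinking
the network.

## Design choices that were genuinely open

* **Sample-SD standardization** (rather than population SD): either choice
  is a pure reparameterization; the binding contract is predictor
  equivalence after back-transformation, which is tested at $10^{-10}$.
* **Destandardizing per completed data set before mixing draws** (the
  per-imputation scalings differ): exact under the linear map, and
  equivalent to any other ordering that respects each data set's scaling.
* **Largest-arm local reference** for studies lacking the global reference,
  with consistency mapping at stage two; the basic-parameter layout keeps
  every mapped contrast exact in every draw.
* **Common-effect stage two as the default** for the design-naive
  approaches: with a handful of studies, $\tau$ (let alone a full
  between-study covariance) is weakly identified; the random-$\tau$ and
  multivariate forms are one argument away.
* **Split likelihood in the design-adjusted model**: the weighted
  relative-effect block and the registry intercept block enter separately,
  without their cross-covariance, matching the model as specified; its
  $w = 1$ and $w \to 0$ limits are verified against the exact closed-form
  posterior of that split linear-Gaussian model.
* **Rows with missing outcomes** are retained for imputation-model
  construction and excluded from the likelihood; evaluation rows that
  cannot be scored — missing outcome or missing covariate values in the
  test registry — are excluded from the metrics and counted in the report.
* **Predictions are not clamped** to the clinical outcome range: the linear
  predictor is unbounded, and clamping would silently distort calibration
  assessments.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run on simulated networks at the
motivating example's scale (about 5,500 patients across five studies) for
recovery checks, with reduced MCMC profiles, $m \le 5$ imputations, and
single-digit bootstrap counts for the demonstration of optimism correction;
these sizes were chosen so the whole battery reproduces the framework's
contracts — metric oracles at $10^{-10}$, recovery within posterior
uncertainty, closed-form pooling identities within Monte-Carlo error — at
desk scale.  For a real analysis, use the full defaults ($m = 20$, long
chains, $B = 200$ bootstraps).

## Known limitations

Continuous outcomes and linear covariate effects only; no fractional
polynomials, splines or tree ensembles; no binary or time-to-event
outcomes (and hence no c-statistic for benefit); no propensity-score or
IPTW adjustment of the registry analyses — regression adjustment only, so
unmeasured confounding in registries propagates into any approach that
uses their relative effects; no power-prior/random-weight variants of the
design adjustment; no imputation of systematically missing predictors; no
single-arm studies.  A single registry can only be cross-validated by
splitting it on a meaningful clustering variable, which the harness leaves
to the user.
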