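---
title: "Adjusting for continuous stratification variables: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting for continuous stratification variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratadjust)
```

## The problem

Randomised trials often stratify randomisation on a continuous prognostic
variable (age, birth weight, a baseline measurement) that has been
dichotomised for the purpose — e.g. birth weight `< 1250 g` versus
`>= 1250 g`. Stratified randomisation induces a correlation between arms on
the stratification variable, so the analysis should adjust for it; the open
question is *in what form*: the randomisation categories, or the underlying
continuous values — and if continuous, assuming what shape of
covariate-outcome relationship?

`stratadjust` provides a simulation laboratory for this question. It
generates trials under known covariate-outcome shapes, randomises them the
way real trials do (permuted blocks within strata), analyses each trial
with the competing adjustment strategies, and scores the strategies on the
standard simulation performance measures.

## Data-generating model

For participant $i$ ($i = 1, \dots, n$; default $n = 200$, the median trial
size for continuous outcomes in published reviews):

* covariate $X_i \sim N(0, 1)$, dichotomised at 0 into
  $X_i^{strat} = 1\{X_i \ge 0\}$;
* treatment $T_i \in \{0, 1\}$ allocated 1:1 by randomly permuted blocks of
  4 within the two strata (or by a fair coin under the
  `randomisation = "simple"` sensitivity setting);
* continuous outcomes
  $Y_i = \beta_0 + \beta_1 T_i + \beta_2 f(X_i) + \beta_3 f(X_i) T_i + e_i$,
  $e_i \sim N(0,1)$; binary outcomes
  $Y_i \sim \text{Bern}\{\text{expit}(\beta_0 + \beta_1 T_i + \beta_2 f(X_i))\}$.

Four shapes $f$ are built in: identity, $e^X$, $X^2$, and the step function
$1\{X \ge 0\}$ that coincides with the randomisation categories. The preset
$\beta_2$ values (0.39/0.78, 0.30/0.60, 0.37/0.74, 1/2) scale each shape so
that moving from the 10th to the 90th percentile of $f(X)$ shifts the mean
outcome by one ("moderate") or two ("strong") residual SDs; under the
identity shape these give $\text{corr}(X, Y \mid T)$ of 0.36 and 0.61. The
treatment effect is 0 (to study test size) or 0.4 (roughly 80% power for an
unadjusted $t$-test at $n = 200$). Interaction scenarios set $\beta_2 = 0$,
$\beta_3 \in \{0.39, 0.78\}$, keeping the *average* treatment effect at 0.4
because $E[X] = 0$.

Missing outcomes follow
$\text{logit}\, P(Y_i \text{ missing}) = \gamma + \log(1.5) T_i +
\log(1.5) X_i + \log(1.5) X_i T_i$ — odds of missingness 1.5 times higher
per SD of $X$ in the control arm, 2.25 in the treated arm — with $\gamma$
calibrated so that 30% of outcomes are missing overall. Because missingness
depends on $X$ and $T$ only, the data are missing at random given the
covariate, and a *correctly specified* covariate-adjusted complete-case
analysis is valid; the interesting failures arise when the adjustment
misspecifies $f$.

### Numerical choices in the generator

The intercept $\gamma$ is found by deterministic quadrature
(`stats::integrate` over $X$, exact average over $T$) plus root finding,
so calibration contributes no Monte Carlo noise; the package's tests check
it against a $10^6$-draw simulation oracle to within 0.001. The same
machinery calibrates the binary-outcome intercept to a 50% control-arm
event rate. The published text does not pin down the binary-outcome
supplementary parameters ($\beta_0$, $\beta_2$); the package therefore
documents its defaults (50% control-arm rate, continuous-case $\beta_2$
presets) as package choices, and no acceptance check targets those cells.

Entry order is generation order; blocks are consumed in that order and a
final partial block is a truncated random permutation, the standard
practice when nothing else is specified. Each scenario has a root seed from
which one seed per replication is pre-drawn (`replication_seeds()`), so
results are identical however the replications are scheduled.

## The five estimators

All five fit a regression of outcome on treatment **without** a
treatment-by-covariate interaction, differing only in the covariate terms:

1. **Unadjusted** — treatment only.
2. **Categories** — treatment + $X^{strat}$, matching the randomisation
   design.
3. **Linear** — treatment + $X$.
4. **FP-2** — treatment + a two-term fractional polynomial of $X$: powers
   $(p_1, p_2)$ from $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (0 meaning $\ln$,
   a repeated power $(p,p)$ meaning $(x^p, x^p \ln x)$), selected per
   dataset by deviance over all 36 pairs with treatment always retained.
   Since $X$ is routinely non-positive it is first shifted by
   $-\min(x) + \delta$, $\delta$ the smallest non-zero gap between order
   statistics — the convention of standard FP software. Ties in deviance go
   to the lexicographically smallest pair. Whether selection should be
   per-dataset or fixed across replications is genuinely open; per-dataset
   selection treats the selection as part of the analysis procedure, which
   is how it would be prespecified in practice, and a `fp_powers` argument
   allows freezing the pair instead.
5. **RCS-5** — treatment + a restricted cubic spline of $X$ with 5 knots at
   the 5th, 27.5th, 50th, 72.5th and 95th percentiles, in the
   truncated-power parameterisation (linear tails, $k - 1 = 4$ columns,
   nonlinear terms normalised by the squared boundary span). The basis is
   deliberately not orthogonalised; collinearity is left to the
   least-squares solver, and the span — the only thing that matters for the
   fit — is unaffected.

Continuous outcomes use OLS with model-based SEs and $t$ intervals on the
residual degrees of freedom ($n_{used}$ minus parameters), the default
output of standard software. Binary outcomes use logistic ML with Wald
intervals (profile intervals would be a defensible alternative; Wald is
what standard adjusted-analysis output reports and is what the acceptance
surface requires only through the unadjusted 2x2, where the two essentially
coincide). Two marginal/conditional companions are included:

* **Standardised risk difference** — after the logistic fit, predict every
  analysed participant's event probability with $T$ set to 1 and to 0 and
  average the difference; the SE propagates the coefficient covariance by
  the delta method (a parametric bootstrap cross-checks it in the tests).
* **Mantel–Haenszel / CMH** — the common odds ratio across the two strata
  with the Robins–Breslow–Greenland SE and the continuity-uncorrected CMH
  test.

Missing outcomes are handled by complete-case analysis or by proper
multiple imputation ($m = 30$ by default) with the imputation model equal
to the analysis model, posterior-draw imputation of the normal-linear
model, Rubin's rules, and Barnard–Rubin degrees of freedom. FP-2 selection
is re-run inside every imputation and every replication, consistent with
treating it as part of the analysis. Replications whose fit fails
(separation, degenerate outcomes, singular designs) carry
`converged = FALSE` and are excluded — with a count — by
`summarise_performance()`.

## Performance measures

Per scenario and method, over $K$ converged replications:
bias $= \bar{\hat\beta} - \beta$, relative bias $100 \cdot$ bias$/\beta$
(reported only for non-null effects), empirical SE (sample SD of the
estimates), coverage of the 95% CI, and the rejection rate of the two-sided
test at $\alpha = 0.05$ — the type-I error when $\beta_1 = 0$, power
otherwise. Monte Carlo SEs use the standard closed forms:
$\text{emp SE}/\sqrt{K}$ for bias, $\text{emp SE}/\sqrt{2(K-1)}$ for the
empirical SE, $\sqrt{\hat p(1-\hat p)/K}$ for proportions.

## What a run looks like

```{r example, eval = FALSE}
cfg <- scenario_config(shape = "exponential", strength = "strong",
                       beta1 = 0.4, n_reps = 5000, seed = 1)
est <- run_scenario(cfg, methods = c("none", "linear", "fp2", "rcs5"))
summarise_performance(est[est$method == "fp2", ], true_effect = 0.4)
```

At 5000 replications the full pattern emerges: the unadjusted analysis is
conservative wherever stratification correlates the arm means (every shape
except $X^2$, whose stratum means coincide); misspecified adjustment
(categories under any smooth shape, linear under $e^X$ or $X^2$) costs
precision with complete data and — the sharper finding — becomes *biased*
once the covariate drives missingness; FP-2 and RCS recover nearly all the
precision and remain unbiased. The package's acceptance tests reproduce the
printed cells of this pattern at the study's own scale of 5000
replications; exploratory work is comfortable at 500–1000 replications with
proportionally wider Monte Carlo error.

## The worked example

The DINO trial (preterm infants randomised to high-DHA versus standard-DHA
diets, randomisation stratified by hospital, sex and birth weight
dichotomised at 1250 g) reported 47/269 infants needing supplemental oxygen
in the high-DHA arm versus 65/269. `dino_worked_example()` reconstructs
that 2x2 and reproduces the unadjusted odds ratio 0.66 (0.44, 1.01) and
risk difference −0.067 (−0.135, 0.001) exactly. The individual-level
covariate data are not publicly available, so the adjusted analyses cannot
be reproduced; `dino_like_trial()` generates a clearly-labelled *synthetic*
dataset of the same shape (538 infants, birth-weight-like covariate
dichotomised at 1250 g, ~24% control-arm event rate) on which all five
methods run end to end. On that fixture, with a genuinely linear
covariate-outcome relationship on the log-odds scale, FP-2 and RCS agree
with the linear adjustment to within 0.02 on the odds-ratio scale — the
expected behaviour when flexibility is not needed.

## What the generator does and does not emulate

The generator reproduces the statistical structure the comparison turns
on: a single standard-normal covariate, its dichotomisation, block
randomisation, four canonical covariate-outcome shapes, and MAR
missingness driven by covariate and arm. Real trials differ in ways that
are out of scope here: multiple stratification variables, skewed or
measured-with-error covariates, unequal allocation (where model-based SEs
are not generally valid and robust SEs are recommended), missingness that
depends on the outcome itself (not MAR), and non-1:1 designs. Passing
tests therefore certify the estimators' behaviour *under the stated
mechanisms*, not under arbitrary real-data pathologies.

## Known limitations

* FP-2 selection is the computational bottleneck (36 model fits per
  replication per method); a full 5000-replication scenario with all five
  methods takes on the order of a minute of CPU.
* The Mantel–Haenszel route reports only the odds ratio — a risk
  difference is deliberately not derived from it.
* Inverse-probability weighting (for treatment or missingness), dual
  adjustment for categories plus continuous values, and
  interaction-robust variance estimators are intentionally not
  implemented.
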