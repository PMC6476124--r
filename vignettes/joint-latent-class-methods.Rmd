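---
title: "Joint latent class modelling of creatinine trajectories and graft failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint latent class modelling of creatinine trajectories and graft failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(graftjlcm)
```

## The model

`graftjlcm` fits a joint latent class mixed model (JLCM) for kidney
transplant recipients. The population is assumed to consist of $G$
homogeneous latent classes; conditionally on class, the serum-creatinine
(SCr) process and the time to graft failure are independent. Three
submodels are tied together in one likelihood:

1. **Membership.** A multinomial logistic submodel gives each subject's
   prior class probabilities
   $\pi_{ig} = \exp(\xi_{g}^\top (1, x_{ci})) / \sum_l \exp(\xi_l^\top (1, x_{ci}))$,
   with the last class as reference. The default membership covariate is
   donor age dichotomized at 60 years.

2. **Trajectory.** Observed SCr $Y_{ij}$ (µmol/L) at time $t_{ij}$ (years
   since transplantation) is a monotone transformation of a latent Gaussian
   process: $H(Y_{ij}; \eta) = \beta_{0g} + \beta_{1g} t_{ij} + \beta_{2g}
   t_{ij}^2 + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij}$, with random
   intercept and slope $b_i \sim N(0, B)$ shared across classes (a
   `classwise_re_scale` switch adds class-specific proportional scalings of
   $B$) and $\varepsilon_{ij} \sim N(0, \sigma^2)$. The quadratic time trend
   allows the non-linear mean profiles the data demand. The density is
   evaluated on the observed scale via the change-of-variables Jacobian
   $dH/dy$.

3. **Survival.** A class-specific two-parameter Weibull proportional-hazards
   submodel, $\Lambda_{0g}(t) = (\zeta_{1g} t)^{\zeta_{2g}}$ and hazard
   $\lambda_{0g}(t)\exp(x_{si}^\top\delta)$, with right censoring (death with
   a functioning graft is censoring, not a competing event) and optional
   delayed entry ($-\log S$ at the entry time is subtracted per class). The
   default hazard covariates are pretransplant NDSA, month-12 proteinuria
   dichotomized at 0.275 g/L, dnDSA, acute rejection, and the dnDSA-by-
   rejection interaction, with coefficients $\delta$ common across classes.

The joint likelihood for subject $i$ is
$\sum_g \pi_{ig}\, f(Y_i \mid g)\, \lambda(T_i\mid g)^{d_i} S(T_i \mid g) / S(T_{0i}\mid g)$,
computed with log-sum-exp stabilization (compiled in C++; an R reference
path is kept and tested for equality).

## Link functions and identifiability

Four monotone link families map SCr to the latent scale: linear, a rescaled
beta CDF, and quadratic I-splines with 5 equidistant or quantile-placed
knots (the equidistant 5-knot I-spline is the retained default
configuration). I-splines are running integrals of normalized M-splines;
storing each basis weight as the square of a free optimizer parameter makes
every iterate monotone by construction. The same squaring is applied to all
positive parameters ($\zeta$, beta-CDF shapes, link scale), and $B$ is
optimized through its Cholesky factor.

Two conventions identify the latent scale:

* the residual SD is fixed at $\sigma = 1$ on the transformed scale, which
  pins the scale of $H$ (the linear link's single coefficient then estimates
  the residual SD in µmol/L);
* the link carries **no free location** — $H(y_{\min}) = 0$ for the spline
  and beta families and the linear link is $y/b$ — because a free link
  intercept would trade off one-for-one against a common shift of the class
  intercepts, leaving a flat likelihood direction and a singular information
  matrix. Class intercepts are unconstrained.

Observations outside the training support are clamped to the boundary
(prediction-time creatinine can exceed the training range).

## Estimation

`fit_jlcm()` maximizes the joint likelihood by BFGS with central-difference
gradients (relative step `1e-5`) on the unconstrained vector. Correctness of
numeric derivatives is guarded by the oracle tests; speed is provided by the
compiled likelihood kernel. The first start is structured — k-means on
per-subject least-squares intercepts/slopes of the crudely transformed
outcome, class-wise regressions for $\beta$, event rates for $\zeta$ — and
subsequent starts are jittered (`n_starts`, default 10; the study-scale
checks use 1-2 starts, which the structured initialization makes
sufficient in practice). Convergence requires the optimizer's relative
tolerance (`1e-10`) and is reported with the gradient sup-norm; tolerances
are package decisions, not reconstructions of the original software's
settings. The variance matrix is the inverse of a numerically symmetrized
observed information (`pracma::hessian`); when it is singular — e.g. a
separation in the membership submodel or an unidentified hazard coefficient
in a small cohort — the fit is returned with `vcov_ok = FALSE` rather than
an error.

After fitting, classes are relabeled so class 1 has the lowest fitted
18-month mean creatinine; the relabeling permutes $\beta$, $\zeta$ and the
random-effect scalings, and re-expresses $\xi$ against the new reference
class, so the reported optimum is unchanged.

Model dimension is chosen by BIC ($-2\ell + p\log N$, $N$ = subjects) over
`G_range`; link families are compared with the discretized AIC: each
measurement's density contribution is replaced by the model-implied
probability of its empirical-quantile bin (30 bins by default, outer edges
at $\pm\infty$; empty bins merged), integrated over the random effects by
9-point tensor Gauss-Hermite quadrature and mixed over classes. Bin
probabilities are invariant to the monotone transformation, which is what
makes likelihoods comparable across link families; the event contribution is
excluded so that a single bin gives exactly zero discretized log-likelihood.
`n_params` in the dAIC remains the full model count.

## Dynamic prediction

For a subject event-free at landmark $s$ (default 1 year: predictions from
data collected up to 12 months), the class posterior combines the prior
membership, the density of the SCr history up to $s$, and survival to $s$.
The predicted failure probability over $(s, t]$ is the mixture
$P(s,t) = \sum_g \hat\pi_g(s) (1 - S_g(t|x)/S_g(s|x))$; it starts at 0,
is nondecreasing, and satisfies the within-class tower identity
$P(s,t) = P(s,s') + (1-P(s,s'))P(s',t)$.

Uncertainty bands draw `n_draws` (default 500) parameter vectors from
$N(\hat\theta, \widehat{\mathrm{vcov}})$ on the unconstrained scale,
recompute the whole curve per draw, and report pointwise 2.5/50/97.5
percentiles. Percentile rather than Wald bands were chosen because they are
bounded in $[0,1]$ and tolerate the asymmetry of transformed parameters; the
median draw curve is reported as the central estimate. The construction of
the published intervals is not documented, so this is a package decision.
`repredict_after_event_update()` re-evaluates the curve after dnDSA or acute
rejection onset: covariates are updated, the landmark moves to the onset
time, and the curve is conditioned on survival to the new landmark.

## Decision rule and evaluation

The at-risk rule flags `predicted_failure` when the upper 95% limit exceeds
50% at any time up to the 10-year horizon, and `predicted_survival` when the
median stays below 30% with the upper limit below 50% throughout. These two
conditions do not partition the outcome space; the gap is reported as an
explicit `indeterminate` category (counted against accuracy), and a
`binary` mode (failure iff the upper limit ever exceeds 50%) reproduces
two-way count arithmetic exactly. Whether the rule should scan the whole
curve or only the horizon endpoint is ambiguous; scanning the whole curve
is the default, matching "included values greater than 50%" over follow-up.
Kaplan-Meier curves and the K-group log-rank test are implemented directly
(product-limit; observed-minus-expected with hypergeometric variance) and
are cross-checked against the survival package in the test suite.

## The synthetic cohort generator

No patient data are distributed; `generate_cohort()` draws cohorts from the
exact generative law the model assumes, so that fitting the generator's own
output is a well-posed recovery experiment. The frozen preset
(`kidney_preset()`) encodes the published study conditions:

* 616 subjects, three classes with post-inclusion proportions calibrated to
  30.7/63.6/5.7%; donors ≥ 60 years (17.8% marginal) shift membership away
  from class 1;
* class baseline SCr of 100/150/150 µmol/L with a slow decrease, a stable
  profile, and a steep rise respectively (linear link with scale 15 µmol/L,
  i.e. residual SD 15 µmol/L; random-effect SDs of 15 and 7.5 µmol/L on the
  observed scale with correlation 0.3, chosen — the source does not report
  them — so that the classes are clearly separated and mean posterior
  class probabilities land in the high-0.8s/0.9s, qualitatively matching the
  published 82.6-89.2% discrimination);
* 10-year baseline failure risks of 5%, 10% and >99% per class, with the
  class-3 Weibull shape set to 3.5 so that no class-3 graft survives seven
  years *and* almost none fails before the 1-year inclusion cutoff (a shape
  near 1 satisfies the first constraint but would put half the class-3
  failures before inclusion, contradicting the published class sizes);
* the published hazard-ratio set (3.27, 2.41, 0.49, 0.78, 15.35) as log
  hazard coefficients, covariate marginals from the published cohort table,
  lognormal month-12 proteinuria with mean 0.166 g/L and ~15% above the
  0.275 g/L threshold;
* visits at months 1/3/6/12/18 with small jitter and 5% missed visits,
  exponential death-with-functioning-graft censoring (rate 0.011/year),
  administrative censoring at 10 years, and a ≥1-year follow-up inclusion
  rule applied by rejection sampling (a `delayed` mode records
  `entry_time = 1` instead, to exercise the left-truncation likelihood).

One caveat is documented rather than hidden: the published class-level
quantities are mutually inconsistent with the published overall failure
count. Integrating the preset's law (`expected_cohort_summary()`) gives an
expected 10-year observed-failure fraction of ~0.17, while the source
cohort reports 11%; the class proportions, class risks, covariate marginals
and hazard ratios cannot all hold together with that marginal. The preset
keeps the class-level calibration, and all generator checks compare
simulation against the *configured* truth. Noise is added on the latent
scale and inverse-mapped, matching the model's error structure; an option
rounds SCr to integer µmol/L to mimic laboratory reporting. Covariates are
drawn independently (donor age acts only through membership); real joint
covariate dependence is unknowable from the published tables and is not
emulated — so passing recovery tests demonstrates correctness of the
machinery under the model's own assumptions, not robustness to model
misspecification, informative visit schedules, or measurement outliers.

## Problem sizes used in the checks

The test suite fits the three-class model once at $n = 600$ (two starts)
and reuses it; the BIC selection study runs 10 seeds over $G \in 1..3$ at
$n = 600$ with single structured starts, and the link-selection study runs
10 seeds of a one-class curved-link generator at $n = 250$ comparing the
linear and beta-CDF families by dAIC. Band-coverage uses 50 fresh subjects
with 300 draws each. These sizes are the package's reproducible defaults
for its own validation experiments; the generator scales to larger cohorts
unchanged.

## Known limitations

* Hazard coefficients are common across classes; class-specific $\delta$ is
  out of scope, as are piecewise-constant and M-spline baseline hazards.
* dnDSA and acute rejection enter the hazard as time-fixed indicators (their
  onset times are used only to update predictions), so the fitted hazard
  ratios inherit the usual immortal-time caveats of that simplification.
* The membership submodel can separate in small cohorts (a binary covariate
  class becoming empty), in which case the information matrix is singular
  and confidence machinery is unavailable for that fit.
* Screening (`screen_covariates()`) refits the joint model per candidate and
  is intended for moderate cohorts; the retained clinical covariate set is
  available directly without screening.
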