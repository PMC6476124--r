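# graftjlcm

Joint latent class modelling of serum-creatinine trajectories and kidney
graft failure, with individualized dynamic risk prediction.

## What problem this solves

After kidney transplantation, serum creatinine (SCr) is the routinely
collected marker of graft function, and clinicians want an early, individual
estimate of the risk of graft failure (return to dialysis or
retransplantation) over the next decade. `graftjlcm` implements the joint
latent class mixed model (JLCM) for this setting: the population is assumed
to consist of G latent subgroups, each with its own SCr time profile and its
own baseline risk of graft failure, with marker and event independent given
class. It is aimed at biostatisticians modelling longitudinal-survival data
in transplantation (or any biomarker/event pairing with the same structure).

The model couples three submodels in one likelihood:

* **membership** — multinomial logistic: π<sub>ig</sub> ∝ exp(ξ<sub>g</sub>ᵀ(1, x<sub>ci</sub>)),
  donor age ≥ 60 as the default covariate;
* **trajectory** — a latent Gaussian process H(Y<sub>ij</sub>; η) =
  β<sub>0g</sub> + β<sub>1g</sub>t + β<sub>2g</sub>t² + b<sub>0i</sub> + b<sub>1i</sub>t + ε<sub>ij</sub>,
  where H is a monotone link (linear, rescaled beta CDF, or quadratic
  I-splines with 5 knots) and b<sub>i</sub> ~ N(0, B);
* **survival** — class-specific Weibull proportional hazards
  Λ<sub>0g</sub>(t) = (ζ<sub>1g</sub>t)<sup>ζ<sub>2g</sub></sup> with
  exp(x<sub>s</sub>ᵀδ) (pretransplant NDSA, month-12 proteinuria > 0.275 g/L,
  dnDSA, acute rejection, dnDSA×rejection), right censoring and optional
  delayed entry.

On top of the fit it provides BIC class-number selection, discretized-AIC
link comparison, posterior classification, landmark dynamic prediction of
P(failure in (s, t] | history up to s) with Monte-Carlo 95% bands,
re-prediction after dnDSA/rejection onset, a confidence-band decision rule
with confusion metrics, Kaplan-Meier/log-rank class comparison, and a seeded
synthetic cohort generator so every stage is testable without patient data.

## Worked example

```r
library(graftjlcm)

cfg <- kidney_preset()                      # frozen 616-subject study preset
gen <- generate_cohort(cfg, seed = 1)
fit <- fit_jlcm(gen$cohort, n_classes = 3, link_family = "linear",
                control = jlcm_control(n_starts = 2, seed = 2))
fit
#> <graft_jlcm> G = 3 classes, 616 subjects, link: linear
#>   logLik: -13595.918  AIC: 27247.836  BIC: 27371.687
#>   class sizes (modal): 187/395/34  convergence: converged

posterior_classification(fit)$summary
#> # A tibble: 3 x 4
#>   class     n proportion mean_posterior
#>   <int> <int>      <dbl>          <dbl>
#> 1     1   187     0.304           0.902
#> 2     2   395     0.641           0.955
#> 3     3    34     0.0552          1.000

hazard_ratios(fit)
#> # A tibble: 5 x 7
#>   term            estimate std.error    hr conf.low conf.high     p.value
#>   <chr>              <dbl>     <dbl> <dbl>    <dbl>     <dbl>       <dbl>
#> 1 ndsa_pre          1.14       0.219 3.12     2.03      4.79  0.000000192
#> 2 prot_gt_0275      1.12       0.218 3.08     2.00      4.72  0.000000268
#> 3 dndsa            -1.11       0.437 0.330    0.140     0.777 0.0112
#> 4 acute_rejection  -0.0620     0.240 0.940    0.587     1.50  0.796
#> 5 dndsa_x_ar        2.15       0.766 8.61     1.92     38.7   0.00497
```

The three classes recover the generating structure: ~31% of subjects with
SCr near 100 µmol/L and ~5% ten-year failure risk, ~63% near 150 µmol/L
and ~10% risk, and a small steeply rising class whose grafts all fail. The
hazard-ratio table reads as in a clinical paper: e.g. pretransplant NDSA
multiplies the failure hazard by ~3.1 (the generating value, 3.27, sits
inside the reported interval); dnDSA and rejection alone are near-null or
protective while their combination is strongly harmful.

Individual prediction from the first year of data, and re-prediction after
a dnDSA + rejection episode at 2.5 years:

```r
cur <- predict_risk(fit, gen$cohort$subjects$subject_id[5],
                    landmark = 1, n_draws = 500, seed = 3)
tail(as.data.frame(cur), 1)
#>    time     point    median    lower95   upper95
#> 91   10 0.1149662 0.1142731 0.08213321 0.1575621

classify_curve(cur, decision_rule())
#> [1] "predicted_survival"

upd <- repredict_after_event_update(fit, gen$cohort$subjects$subject_id[5],
                                    landmark = 1, dndsa_time = 2.5,
                                    ar_time = 2.5, n_draws = 500, seed = 3)
autoplot(upd)   # median curve with its 95% band
```

The subject's 10-year failure probability is ~11% (95% band 8-16%), below
the 30%/50% decision thresholds, so the rule calls predicted survival; the
update multiplies the hazard by exp(δ̂ for dnDSA + rejection + interaction)
and shifts the curve upward accordingly.

## Layout

* `R/` — cohort I/O and validation, link functions, latent-class and
  survival submodels, joint estimation, dAIC, dynamic prediction,
  evaluation, synthetic generator, tidy/glance/autoplot methods,
  pipeline commands; `src/` — the compiled likelihood kernel.
* `inst/cli/graftjlcm.R` — `simulate | fit | predict | evaluate`
  subcommands over YAML run configurations.
* `vignettes/joint-latent-class-methods.Rmd` — model, identifiability
  conventions, numerical choices, generator calibration and its documented
  caveats, known limitations.
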