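# pubgrowth

Determine the timing of pubertal onset from longitudinal growth data.

Pediatric cohorts often measure height routinely but assess clinical
pubertal staging (Tanner breast stages in girls, testis length in boys)
only in a subset of children, or not at all — staging is intrusive for
adolescents and hormone assays are expensive. `pubgrowth` implements a
two-stage statistical pipeline for epidemiologists working with such
cohorts:

1. **Growth stage.** A SITAR (Super-Imposition by Translation And
   Rotation) nonlinear mixed-effects model describes every child's height
   curve as a shifted, time-scaled copy of a shared spline curve,

   *y<sub>ij</sub>* = (*a*₀ + *a*<sub>C</sub> + *a*<sub>i</sub>) +
   *h*{(*t*<sub>ij</sub> − *b*<sub>C</sub> − *b*<sub>i</sub>)
   e<sup>*c*<sub>C</sub> + *c*<sub>i</sub></sup>} + ε<sub>ij</sub>,

   with per-child random effects for size *a* (cm), timing *b* (years) and
   intensity *c* (log velocity scale), plus cohort fixed effects.  From the
   fitted curves come each child's age at peak height velocity (aPHV), the
   peak height velocity (PHV), the growth-spurt takeoff age, and
   delta-method cohort contrasts with Wald tests.

2. **Onset stage.** Clinical staging defines an interval-censored onset
   age per child (last pre-pubertal to first pubertal visit; one-sided
   censoring where onset precedes or outruns follow-up).  Onset age is
   regressed on the growth markers — and on overweight status at takeoff,
   classified through an adult-equivalent (ISO) BMI reference — by
   maximum likelihood under a Gaussian model,
   *T*<sub>i</sub> ~ N(*x*<sub>i</sub>ᵀβ, σ²), with an L1-penalized
   variant for variable selection.  Predictive ability is summarized by
   10-fold cross-validated interval-overlap agreement: a prediction agrees
   when the one-year window centred on it overlaps the observed interval
   (children with observed intervals ≥ 1.5 years are excluded).

Because the motivating cohort data are not public, the package ships a
calibrated synthetic multi-cohort generator (`simulate_cohort()`) that
emulates the study design — three cohorts, 6–12-month growth visits over
ages 7–19, staging from age 8, dropout — with a full truth table, so every
stage is testable end to end.

## Worked example

```r
library(pubgrowth)
library(dplyr)

sim <- simulate_cohort(sim_config(n_children = 120, seed = 7))
sim
#> <pubgrowth_sim>  306 children (177 with pubertal data), 4716 growth rows; seed 7

girls <- filter(sim$growth, sex == "F", age_years >= 7, age_years <= 19)
fit <- fit_sitar(girls)
fit
#> <sitar_fit>  124 children, 1814 obs, 16 basis df (penalized, lambda = 0.613)
#>   residual SD 0.690 cm; RE SDs a 5.34 cm, b 1.41 y, c 0.122
#>   cohort offsets vs DIPP:
#>  cohort        a         b          c
#>   STRIP 1.817783 0.2042705 0.05445405
#>   Laplace logLik -2765.92; converged: TRUE (326 iterations)

markers <- growth_markers(fit)
head(markers, 3)
#>   child_id  cohort  aphv   phv   size takeoff_age n_measurements
#> 1 DIPP_0004 DIPP    12.5  7.42   2.12        9.63             17
#> 2 DIPP_0007 DIPP    11.8  9.63  -4.82        9.68             16
#> 3 DIPP_0009 DIPP    12.4  8.64   1.69        9.94             16
```

The fitted residual SD (0.69 cm) is measurement-scale noise; the
random-effect SDs say children vary by about 5.3 cm in size and 1.4 years
in spurt timing. The STRIP-like cohort is estimated 1.8 cm taller than the
reference at all ages (generating value 1.7 cm).

```r
intervals <- onset_intervals(filter(sim$pubertal, sex == "F"))
bfit <- fit_bmi_trajectory(filter(sim$growth, sex == "F", !is.na(bmi)))
d <- inner_join(select(intervals, child_id, left, right, censor_type),
                overweight_at_takeoff(markers, bfit, "F"),
                by = "child_id") |>
  filter(!is.na(overweight))

onset <- fit_aft(d, "extended_girls")
tidy(onset)
#>   term            estimate std.error statistic  p.value
#> 1 (Intercept)        5.60      2.51       2.23  0.0256
#> 2 aphv               0.721     0.194      3.72  0.000196
#> 3 phv               -0.414     0.117     -3.55  0.000385
#> 4 overweight       -10.3      8.51      -1.21   0.227
#> 5 aphv:overweight    0.784     0.748      1.05  0.294

preds <- kfold_predict(d, "extended_girls", k = 10, seed = 7)
agreement(d, preds)
#> <pubgrowth_agreement>  55 evaluated (0 excluded: interval >= 1.5 y; 10 not interval-censored)
#>   agreements: 38 (69.1%)
```

Later onset goes with later aPHV (+0.72 years per year) and lower PHV
(−0.41 years per cm/year); out-of-fold predictions land within a year of
the observed onset interval for 69.1% of evaluable girls. The whole
workflow — simulation or CSV input, both model presets, lasso selection,
contrasts, artifacts and a markdown report — is wrapped in
`run_full_pipeline(run_config(...))`, and `autoplot()` methods draw the
growth/velocity curves and the observed-versus-predicted interval plot.

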