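# metabodyn

Quantitative analysis toolkit for long-term diet-intervention studies in
rats: damped-oscillation modelling of glucose/insulin tolerance curves,
derived glycemic parameters and dysglycemia classification, metabolic
phenotyping indices (HOMA-IR, normalized caloric intake, adipocyte size
classes), the variance-gated factorial statistics layer, and a MALDI
imaging-MS strong-signal metabolite screen with offline adduct-mass
annotation. A synthetic cohort generator emulates the full study design
(4 interventions × 2 sexes, n = 8/group, GTT sampling at
0/15/30/45/60/90/120/240 min, ITT at 0/15/30/45/60/90/120/180 min), so the
whole pipeline runs, and is tested, without any animal data.

It is written for biostatisticians and physiologists analysing rodent
metabolic phenotyping data who want the curve model, the derived parameters
and the multiple-testing conventions in one tested, scriptable place.

## The model

Blood glucose after a bolus is modelled as a damped harmonic return to a
setpoint:

    G(t) = G0 + A · exp(−α t) · sin(2π t / T + φ)

with t in hours: setpoint G0 (mg/dL), amplitude A, damping coefficient α
(1/h), basic period T (h), phase φ. From the fit the package derives the
standard tolerance-test parameter set — fasting G(0), peak G_max at t_max,
2-h glucose G(2), initial rate G′(0), steepest descent G′_I at t_I with
level G_I, and the closed-form model AUC (ITT analogues: H(0), H_min at
t_min, H0, H′(0)) — plus the trapezoid AUC of the measured points.
Dysglycemia labels follow the diagnostic bands: fasting ≥ 126 mg/dL or 2-h
≥ 200 mg/dL is diabetes, fasting [100, 126) or 2-h [140, 200) prediabetes.

## Worked example

```r
library(metabodyn)

# a noise-free GTT curve from known dynamics, and its recovery
ser <- generate_gtt_curve(
  list(G0_setpoint = 100, A = 80, alpha = 0.8, T_period = 3, phi = 0.2),
  grid_min = c(0, 15, 30, 45, 60, 90, 120, 240), noise_sd = 0)
fit <- fit_damped_oscillator(ser)
fit
#> <damped_osc> GTT fit: G0 = 100.0 mg/dL, A = 80.0, alpha = 0.8 /h, T = 3 h, phi = 0.2
#>   R^2 = 1, residual SD = 0 mg/dL, converged = TRUE

round(derive_parameters(fit)[, c("G_fasting", "G_max", "t_max", "G_2h",
                                 "Gprime_I", "t_I", "AUC_model")], 2)
#>   G_fasting  G_max t_max  G_2h Gprime_I  t_I AUC_model
#> 1    115.89 150.89  0.48 84.69   -71.98 1.06    435.71

classify_dysglycemia(126, 150)$label   # "diabetes"  (fasting criterion)
homa_ir(90, 9)                         # 2  = 90 × 9 / 405
adduct_mz("C10H13N4O8P", "M+K")        # 387.0103  (IMP [M+K]+)
```

G(0) = 115.9 mg/dL is the modelled fasting value, the curve peaks at 150.9
mg/dL half an hour after the bolus, the steepest glucose fall (−72 mg/dL/h)
occurs at ~64 min, and the area under the modelled curve over the 4-h test
is 435.7 mg/dL·h.

The full workflow lives under `analysis/` as numbered scripts:

```sh
Rscript analysis/01_simulate.R     # synthetic cohort -> results/data/*.csv
Rscript analysis/02_fit_curves.R   # group GTT/ITT fits + glycemic parameters
Rscript analysis/03_phenotype.R    # HOMA-IR, caloric intake, adipocyte classes
Rscript analysis/04_group_stats.R  # Levene-gated ANOVA / post-hocs, RM ANOVA
Rscript analysis/05_ims_screen.R   # alignment, strong signals, KW+Dunn, PCA
```

Stage 2, for example, prints the week-18 group parameter table
(synthetic cohort, seed 20230901):

```
  HFHSD+L_F  G(0)=124.8 G(2)=229.5 G_max=243.1 t_max=1.41h alpha=0.36 T=8.81h  diabetes
  STD_F      G(0)= 98.1 G(2)= 97.5 G_max=147.5 t_max=0.60h alpha=1.05 T=3.35h  normal
  ...
```

— liraglutide-treated females the slowest to return to setpoint and
diabetic on the 2-h criterion, standard-diet animals the fastest: the
qualitative pattern the generator encodes.

## Layout

- `R/` — the package: synthetic cohort, oscillator fitting and derived
  parameters, phenotyping, inference layer, IMS screen, CSV/config IO
- `analysis/` — the numbered workflow scripts (thin drivers over `R/`)
- `tests/testthat/` — unit, property and end-to-end acceptance tests
- `vignettes/metabolic-dynamics.Rmd` — the methods vignette: model,
  assumptions, parameter conventions, generator realism, known limits
- `inst/extdata/` — group-dynamics fixture, annotation table, config template
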