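# ccindex

Scoring and prognostic evaluation of cumulative postoperative morbidity
after liver transplantation (LT).

Single-grade complication summaries discard most of what happens to a
transplant recipient between surgery and discharge. The comprehensive
complication index (CCI) instead aggregates *every* graded complication of
the post-transplant course into one number on a 0–100 scale:

```
CCI = sqrt(wC1 + wC2 + ... + wCx) / 2
```

where each complication contributes a weight `wC` determined by its
Clavien–Dindo grade (I < II < IIIa < IIIb < IVa < IVb < V). A single
grade I complication scores 8.7; a single grade V (death) scores 100, the
top of the scale. `ccindex` implements the index together with the
LT-specific grading conventions (retransplantation during the first
hospitalization = IVa + IIIb; multiorgan failure = IVb; primary
non-function = IVa; early allograft dysfunction = II; renal replacement
therapy = IVa; mild renal dysfunction and myelotoxicity = I), and the
full prognostic pipeline built on top of it:

- **Diagnostics** — ROC analysis of CCI against the MELD, D-MELD, BAR and
  EAD comparator scores for 90-day and 1-year graft loss: concordance
  AUC with DeLong standard errors, quartile / ninth-decile cut-offs,
  sensitivity, specificity and diagnostic odds ratios
  (DOR = sens·spec / ((1−sens)(1−spec))).
- **Survival** — Kaplan–Meier graft survival over five CCI risk bands
  (0–12.2, 12.3–29.6, 29.7–47.3, 47.4–84.9, 85–100), log-rank tests, and
  univariable / multivariable Cox proportional-hazards models with
  backward Wald covariate elimination (MELD and D-MELD are kept out of
  the same model as a collinearity guard).
- **Synthetic cohorts** — a generator producing complete synthetic LT
  cohorts: per-grade Poisson complication counts calibrated to a target
  highest-grade distribution, covariates, and graft-loss times from a
  Weibull proportional-hazards model whose linear predictor includes the
  CCI (default hazard ratio 1.05 per CCI point). Two presets
  (`training_like`, `validation_like`) emulate a multicentre and a
  single-centre cohort profile, so every pipeline stage runs without any
  patient data.

The intended users are clinical researchers evaluating post-transplant
risk scores and methodologists who need a reproducible, fully synthetic
test bed for survival-score validation pipelines.

## Worked example

```r
library(ccindex)

# one patient's course: EAD, then retransplantation, then myelotoxicity
ev <- data.frame(patient_id = "LT042",
                 grade = c("II", "IVa", "IIIb", "I"),
                 label = c("EAD", "retransplantation",
                           "retransplantation", "myelotoxicity"))
compute_cci(ev)
#> CCI [LT042]: 58.7 (4 complications)

# a fully synthetic single-centre-style cohort, scored and evaluated
res <- run_pipeline(run_config("validation_like", n_patients = 1000,
                               seed = 42))
res$diagnostics$day365[[1]]
#> cci: AUC 0.73 +/- 0.04 (95% CI 0.65-0.80), 57 events / 943 non-events
#>   cutoff   12.2: sens  86.0  spec  30.3  DOR      2.7
#>   cutoff   26.2: sens  71.9  spec  54.3  DOR      3.0
#>   cutoff   39.6: sens  57.9  spec  77.0  DOR      4.6
#>   cutoff   48.9: sens  43.9  spec  92.0  DOR      9.0
```

The CCI of patient LT042 is 58.7: the square root of the summed weights
of grade II (1750), IVa (7200), IIIb (4550) and I (300) events, halved.
In the synthetic cohort the CCI discriminates 1-year graft loss with AUC
0.73, and discrimination sharpens as the cut-off rises (DOR 2.7 at the
first quartile up to 9.0 at the ninth decile) — the qualitative pattern a
cumulative morbidity score should show. The comparator scores stay near
AUC 0.5 here because the preset draws them independently of the
complication process:

```r
res$cox_multivariable$model$table[, c("covariate", "hr", "p_value")]
#>   covariate       hr      p_value
#> 1       bar 1.046134 5.680317e-03
#> 2       cci 1.045872 1.064761e-48
```

The backward-Wald Cox model recovers the generative hazard ratio of
~1.05 per CCI point. The five CCI risk bands separate strongly on the
log-rank test (chi-square 346.3 on 4 df in this run).

A thin command-line wrapper is included:

```sh
Rscript inst/cli/cci-pipeline.R run --preset training_like --n 1000 \
    --seed 7 --out reports/
```

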