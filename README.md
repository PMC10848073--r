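# gcpanel

Composite gene-expression panel scoring for predicting glucocorticoid (GC)
resistance in multiple sclerosis relapses.

High-dose GC pulses are the first-line treatment of MS relapses, yet many
relapses do not respond clinically (no EDSS change four weeks after ≥ 1
pulse). `gcpanel` is for biostatisticians and translational researchers who
want to build, audit or stress-test the kind of predictor proposed for this
problem: a 12-gene whole-blood qPCR panel (PGAP3, LDLRAP1, SNPH, DDX54,
ABHD8, FASN, SNX2, RHOT1, EAF2, ANXA1, AIM2, N4BP2L2) dichotomized at fixed
ROC cut-offs and summed into a 0–12 score.

## The model

For gene *j* with relative expression
*x<sub>j</sub>* = Ct<sub>gene</sub>/Ct<sub>ACTB</sub> and cut-off
*c<sub>j</sub>*, the composite score is

    S = Σⱼ 1[ xⱼ ≥ cⱼ ]   for genes up-regulated in GC-resistant relapses
      + Σⱼ 1[ xⱼ < cⱼ ]   for down-regulated genes,     S ∈ {0, …, 12}

Per-gene cut-offs (and the score's own cut-off) are chosen on the empirical
ROC curve as the threshold maximizing sensitivity subject to a specificity
floor (default ≥ 80%); the AUC is the tie-corrected Mann–Whitney statistic
U/(n₁n₂). The score then enters a logistic regression adjusted for sex,
age, disease duration, immunotherapy class, EDSS before GC and GC dose
(optionally recruitment center), reported as odds ratios with Wald 95% CIs.

Because no patient-level data are publicly deposited, the package includes
a calibrated synthetic cohort generator: a single-factor Gaussian
latent-liability model whose probit calibration reproduces each gene's
published per-group positivity rates exactly for any choice of the shared
correlation loading, plus covariates drawn from the published baseline
marginals of the pooled 47-patient two-center cohort. An exact
Poisson-binomial score distribution serves as the independence-model
oracle. See `vignettes/panel-methods.Rmd` for the full methods account.

## Worked example

```r
library(gcpanel)
report <- run_pipeline(run_config(seed = 7, legacy_cutoff = 8.8))
print(report)
```

```
GC-resistance panel run (gcpanel 0.1.0, seed 7, config a20c656e)
Cohort: 47 patients (31 sensitive / 16 resistant), 47 scored

Composite score classifier (16 cases / 31 controls)
  AUC = 0.800; cutoff >= 9: sensitivity 31.2%, specificity 93.5%

Adjusted logistic model:
Logistic regression (n = 47, logLik = -15.09)
           predictor      coef odds_ratio ci_lower ci_upper p_value
               score  0.631000      1.880   0.9670     3.65 0.06290
              female -1.410000      0.245   0.0258     2.33 0.22100
                 age -0.041200      0.960   0.8340     1.10 0.56600
    disease_duration -0.871000      0.419   0.2190     0.80 0.00841
 immunotherapy_group -0.634000      0.530   0.1090     2.59 0.43300
          edss_prior -0.491000      0.612   0.1600     2.33 0.47200
          gc_dose_mg -0.000425      1.000   0.9990     1.00 0.12600
```

Reading this: a synthetic 47-patient cohort (31 GC-sensitive, 16
GC-resistant) was generated with the panel's calibrated firing rates, every
patient scored 0–12, and the legacy score cut-off 8.8 applied as score ≥ 9
— here catching 31.2% of resistant patients while keeping 93.5% of
sensitive patients negative, with a score AUC of 0.800. Each unit of score
multiplies the adjusted odds of GC resistance by 1.88 (95% CI 0.97–3.65) in
this replicate; at n = 47 the interval is wide, which is exactly the
sampling behavior such a cohort implies. `write_report(report, "out/")`
exports the full JSON/Markdown report, including per-gene operating points
and baseline statistics.

Individual stages are available as plain functions
(`expression_matrix()`, `binarize()`, `composite_score()`,
`score_classifier()`, `fit_logistic()`, `generate_cohort()`, …), and a thin
command-line front end with `simulate` / `normalize` / `score` / `stats` /
`fit` / `run` subcommands ships in `inst/cli/gcpanel.R`.

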