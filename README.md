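# protscore

Sex-specific proteomic extension of Cox survival risk scores.

## What this is for

Ten-year cardiovascular risk scores built on age, systolic blood pressure,
total and HDL cholesterol and smoking leave residual risk on the table, and
the biology behind events differs between men and women. `protscore` is for
biostatisticians and epidemiologists who want to test whether a large plasma
proteomic panel (Olink-style NPX values) improves such a score when the
proteins are **selected separately per sex**, and to quantify that
improvement with the field's standard validation battery. Because
individual-level biobank data cannot be shipped, the package includes a
seeded synthetic-cohort generator with known ground truth, so the entire
workflow is runnable and testable offline.

## The method in brief

For each sex stratum of a derivation set (a 70/30 sex-stratified split):

1. **Stability selection.** For b = 1..B (default 200) bootstrap resamples,
   tune the LASSO-Cox penalty λ by event-stratified ten-fold
   cross-validation (minimum mean partial-likelihood deviance), refit at
   λ*, and record proteins with nonzero coefficients. Select proteins with
   frequency ≥ ⌈0.95·B⌉ (190 of 200). Clinical covariates are unpenalized,
   so selection is incremental over the base score.
2. **Risk models.** Per sex, fit Cox proportional-hazards models (Breslow
   ties) for the clinical covariates alone and with the selected proteins;
   10-year absolute risk is `1 − exp(−H0(10) · e^lp)` with `H0` the Breslow
   baseline cumulative hazard.
3. **Validation.** On the held-out 30%: Harrell's C with U-statistic CIs,
   the correlated C-index difference test (joint U-statistic covariance,
   normal approximation), categorical NRI over the 0–5% / >5–10% / >10%
   risk bands, IDI, decile calibration with Kaplan–Meier observed risks,
   horizon ROC curves, per-protein adjusted hazard ratios per SD with
   sex-interaction tests, and per-protein incremental C.

Censoring before the 10-year horizon is handled throughout by Kaplan–Meier
inverse-probability-of-censoring weighting (complete-case as an option).

## Worked example

```r
library(protscore)

res <- run_pipeline(run_config(seed = 42))   # packaged demo world
print(res$evaluation)
```

```
<eval_report>
  male    n=809 events=39  C 0.676 -> 0.782 (p=0.029)  NRI 25.5%  IDI 0.190
  female  n=991 events=44  C 0.704 -> 0.826 (p=0.0015)  NRI 30.9%  IDI 0.054
  overall n=1800 events=83  C 0.689 -> 0.805 (p=0.00018)  NRI 28.1%  IDI 0.117
```

The demo world has 6,000 participants, 60 block-correlated proteins and six
truly informative proteins (two shared, two male-only, two female-only, all
at hazard ratio 1.8 per SD). Each line is a validation-set stratum: the
C-index of the clinical base model, the C-index after adding that sex's
selected proteins, the p-value of the correlated C-index comparison, the
total categorical net reclassification improvement, and the integrated
discrimination improvement. The selected sets themselves live in
`res$selection`:

```r
res$selection$overlap
#> $shared      [1] "P001" "P011"
#> $male_only   [1] "P021" "P031" "P043"
#> $female_only [1] "P035" "P041" "P044" "P051"
```

All six planted proteins are recovered (P001/P011 shared, P021/P031 male,
P041/P051 female); the three extras are recurrent false positives of the
default CV-min λ rule at this sample size — the methods vignette discusses
this behavior and the stricter 1-SE option. `make_report(res, "report.md")`
renders a markdown summary (baseline table with t-test/χ² comparisons,
performance table, hazard-ratio forest data, incremental C). A command-line
front end is installed as `exec/protscore` with subcommands `simulate`,
`select`, `run-all` and `report`.

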