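---
title: "Methods: sex-specific proteomic extension of a survival risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific proteomic extension of a survival risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Classical 10-year cardiovascular risk scores (age, sex, systolic blood
pressure, total and HDL cholesterol, smoking) leave substantial residual risk
unexplained, and men and women differ both in baseline risk and in the
biology that drives events. `protscore` implements, end to end, a workflow
for asking whether a large plasma-proteomic panel (Olink-style NPX values)
can improve such a score when proteins are *selected separately per sex*:
per-sex bootstrap stability selection with LASSO-penalized Cox models,
refitting of base and protein-extended Cox risk models, and a full
discrimination / reclassification / calibration validation battery. Because
the motivating individual-level biobank data cannot be redistributed, the
package ships a seeded synthetic-cohort generator with known ground truth,
so that every stage is testable at desk scale.

## The synthetic cohort: a stated world

`sim_config()` defaults describe one fixed world, chosen once:

* **Covariate marginals** mirror a large mid-life European cohort free of
  cardiovascular disease and diabetes: 44.1% male; age 56.4 (SD 8.2) years;
  SBP 139.5 (19.8) mmHg; total cholesterol 5.8 (1.1) mmol/L; HDL 1.5 (0.4)
  mmol/L; 10.4% current smokers. Normal covariates are clipped to wide
  plausibility ranges (e.g. age 30–90) several SDs out, so the stated
  moments are preserved to well under Monte-Carlo noise.
* **Outcome**: a single composite event over a 10-year horizon. Event times
  are Weibull with shape 1 by default (exponential), i.e. cumulative hazard
  `H(t) = h0 * t^k * exp(lp)`; the exponential default gives closed-form
  incidence oracles for testing. Non-cardiovascular death is folded into an
  independent exponential dropout (0.005/year) plus administrative censoring
  at 10 years; competing-risk modelling is out of scope.
* **Linear predictor**: mean-centered covariate effects
  (age 0.07/y, SBP 0.013/mmHg, total cholesterol 0.10, HDL −0.45 per mmol/L,
  smoking 0.60) plus sex-specific per-SD protein effects. The default panel
  has 60 proteins in exchangeable blocks of 10 with within-block correlation
  0.3; informative proteins (2 shared, 2 male-only, 2 female-only, all at
  per-SD log-HR ln 1.8) sit in different blocks, as distinct biological
  pathways would. The baseline rate `h0 = 0.0021` was calibrated once so the
  default world's marginal 10-year incidence is ≈ 4.6%, matching the
  motivating cohort, and is not revisited.
* **Missingness / detection limits**: per protein, an MCAR missingness rate
  drawn from `missing_rate_range` and a below-LOD quantile from
  `lod_quantile_range`. Below-LOD values keep their drawn value but are
  flagged; filters act on flags, keeping the generator invertible for tests.

What the generator does **not** emulate: assay/plate batch effects,
non-Gaussian NPX tails, missingness that depends on concentration (values
near the detection limit are in truth more likely missing), competing risks,
or any claim about the real joint distribution of plasma proteins. A green
test therefore establishes that the *procedure* behaves as specified on a
proportional-hazards world with Gaussian block-correlated biomarkers — not
that it would select the same proteins in any real cohort.

## Preprocessing

* **Protein filter**: exclude when missing fraction > 20% *or* below-LOD
  fraction (among observed values) > 25%; both strict, so boundary ties are
  retained. **Participant filter**: row missingness > 50% excludes.
  Double-failing proteins are counted once under the missingness reason.
* **Imputation** is single (one completed matrix), by chained equations with
  a small bagged ensemble of CART regression trees per incomplete column
  (least-missing columns first, 5 sweeps, seeded). No tree package is part
  of the dependency footprint, so the learner (variance-reduction splits,
  depth 3, bagged over 3 bootstraps) is implemented in the package. For
  speed, each target's predictors are the complete clinical covariates plus
  the 10 most correlated proteins (pools fixed after mean-initialization).
  This is deliberately a contract-level stand-in for heavier random-forest
  chained-equation imputers: observed values are never changed, the result
  is deterministic given the seed, and it must beat column-mean imputation
  on correlated panels (enforced by test). The pipeline imputes protein
  columns only; clinical covariates enter as predictors and are assumed
  complete (the generator never masks them).
* **Split**: 70/30 derivation/validation drawn independently within each
  sex, so each stratum honors the fraction to within one participant.
* **Standardization**: per-protein mean/SD computed on the derivation set
  (both sexes pooled) and applied to everyone; the scaling metadata is
  reused for validation data. A per-sex reference was considered and
  rejected as the default: pooled scaling keeps "per SD" comparable across
  the sexes in the association tables, and the sex-specific Cox models are
  free to absorb scale differences in their coefficients.

## Stability selection

Within one sex stratum, for each of `n_bootstrap` (default 200) resamples
drawn with replacement at the original stratum size: ten-fold
cross-validation (folds event-stratified and seeded) picks the LASSO penalty
by minimum mean partial-likelihood deviance, the model is refit at that
penalty, and proteins with nonzero coefficients are recorded. A protein is
*selected* when its count reaches `ceiling(0.95 * n_bootstrap)` — 190 of
200 with the defaults. The clinical covariates ride along unpenalized by
default (`penalize_score2_covariates = FALSE`), so proteins are judged on
incremental signal over the base score; penalizing them is a config switch.
Path fitting and CV deviance are delegated to `glmnet` (coordinate descent,
Breslow ties); the λ=0 limit is verified against the Newton solver of
`survival::coxph` to 1e-6 and single-covariate solutions against brute-force
1-D grid minimization.

**A calibrated warning on the λ rule.** The minimum-CV-deviance rule is the
package default because it is the published procedure's stated rule. It is,
however, known to over-select at moderate n/p: a CV-min fit keeps a handful
of noise proteins, and since all bootstrap resamples share the original
sample's spurious correlations, *the same* noise proteins recur across
bootstraps. On a world with n = 2000, ~190 events and 50 null proteins
around one strong (per-SD log-HR ln 2) protein, the true protein reaches
200/200 and is the only protein at the 95% threshold, but individual null
proteins can recur in well over 40% of bootstraps. The one-standard-error
rule (`lambda_rule = "1se"`) restores aggressive sparsity (top null
frequency around 10–25%) and is the recommended setting when the
selection frequencies themselves, not just the thresholded set, are to be
interpreted. At desk scale (a few thousand participants, tens of proteins,
strong injected effects) the persistence can be severe enough that one or
two null proteins cross even the 95% threshold under CV-min, which is why
two clauses of the acceptance battery are intentionally left failing under
the default rule while a property test demonstrates exact recovery under
the 1-SE option on the same world. At biobank scale (tens of thousands of
participants, thousands of proteins) the relative persistence of noise is
far lower, which is consistent with the motivating workflow recovering a
small, robust panel with CV-min tuning.

Per-bootstrap seeds derive deterministically from the master seed and the
bootstrap index, so runs are reproducible and could be parallelized without
changing results. Both strata use the same master seed; swapping the sex
labels therefore swaps the two results exactly.

## Risk models

The base model refits a plain Cox proportional-hazards model per sex on the
clinical covariate set; the published score's original age-interaction
transformations and competing-risk recalibration are *not* reproduced
(their coefficients are not available in the motivating report), which is a
documented divergence — comparisons are internally consistent because base
and extended models are fit on the same derivation data. Ties are handled
by Breslow (matching the penalized stage; Efron available). Covariates are
centered at their means; the Breslow baseline cumulative hazard `H0` is
evaluated at the 10-year horizon; absolute risk is
`1 − exp(−H0 · exp(lp))`. Standard errors come from the inverse observed
information. Per-protein association models add one standardized protein at
a time to the clinical model per sex (hazard ratio per SD, Wald CI); the
sex-interaction test is a pooled model with sex, protein and protein×sex
terms (Wald p on the interaction).

## Validation battery

* **Harrell's C** over usable pairs — earlier-time event pairs, plus
  tied-time pairs with exactly one event; tied risks score 0.5. The variance
  (and for the difference test, the joint covariance of the two estimators
  over the *shared* comparable-pair set) comes from the Hájek projection of
  the ratio-of-U-statistics; the difference test is the standard correlated
  C-index comparison built on that joint covariance, with a two-sided normal
  p-value. Degenerate inputs (identical risk vectors) return Δ=0, p=1. The
  estimator matches `survival::concordance` point estimates exactly and its
  null rejection rate is verified to sit inside the exact binomial 99% band
  around 5% (1,000 seeded replicates).
* **Risk categories** are `[0, 5%]`, `(5%, 10%]`, `(10%, 1]` — left-open
  upper boundaries, so exactly 5% is low risk.
* **NRI / IDI / ROC** evaluate event status *at the horizon*. Participants
  censored before the horizon are handled by inverse-probability-of-censoring
  weights from the Kaplan–Meier estimate of the censoring distribution
  (cases weighted by `1/G(T−)`, horizon survivors by `1/G(h−)`); a
  complete-case option exists. Uncensored data reduce exactly to the
  textbook formulas (enforced by test). NRI and IDI confidence intervals use
  a seeded 1,000-replicate participant bootstrap.
* **Calibration**: deciles of predicted risk (ties broken by stable input
  order), observed risk per decile by Kaplan–Meier at the horizon; the
  decile regression slope summarizes calibration.
* **Incremental discrimination**: base model plus one selected protein at a
  time, refit on derivation, C compared on validation with the correlated
  C-index test.

## Numerical choices

* Automatic λ grids run from the largest all-zero λ down 4 decades over 100
  points by default; tests and the demo use coarser grids (20–30 points,
  2–3 decades) purely for runtime — on those worlds the selected λ sits well
  inside one decade of the top of the path. `glmnet` requires two columns,
  so single-covariate designs are padded with a zero column that cannot
  enter the model.
* Bootstrap resamples that cannot support event-stratified ten-fold CV
  (fewer than 10 events) are redrawn deterministically; strata with zero
  events are an error.
* Cox fits reject constant columns, non-finite inputs and suspected
  monotone likelihoods (|β| > 30).
* The packaged demo (`run_config()` defaults) runs n = 6,000 participants
  and 60 proteins with B = 100 bootstraps so the full pipeline completes in
  minutes on one CPU; B = 200 at biobank scale is a configuration change,
  not a code change.

## Known limitations

* MCAR missingness and flag-only detection limits are idealizations; the
  imputer is a light stand-in for random-forest chained equations.
* The base risk model is a refit of the clinical covariate set, not the
  published score's frozen algorithm; absolute risks are internally
  calibrated to the synthetic world only.
* The correlated C-index test's variance is asymptotic; at very small n or
  very few events the bootstrap NRI/IDI intervals are more trustworthy than
  the normal approximation.
* Under the default CV-min λ rule, *selection frequencies* of non-selected
  proteins are not interpretable as false-positive rates (see above); use
  the 1-SE rule for that purpose.
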