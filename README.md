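# iapagree

Agreement analysis for paired venous pressure measurements stratified by
intra-abdominal pressure (IAP).

In intensive care, central venous pressure (CVP, superior vena cava) is
sometimes approximated by a femoroiliac venous pressure (FIVP) read from
a femoral line. The two agree closely while the abdomen is soft, but
raised intra-abdominal pressure superimposes itself on the femoroiliac
reading and FIVP starts to overestimate CVP. `iapagree` provides the
statistical toolkit for this method-comparison problem:

* **Concordance** — one-way random-effects single-measurement intraclass
  correlation ICC(1,1), estimated from the ANOVA mean squares as
  `(MSB − MSW)/(MSB + MSW)`, with the exact F-based (Searle) confidence
  interval and Landis–Koch interpretation (`icc_oneway()`, `icc_ci()`,
  `landis_koch_label()`).
* **Threshold scan** — the ICC profile of the subsets with IAP below
  each integer threshold, and selection of the best cutoff
  (`icc_profile()`, `best_cutoff()`), with a selection rule that prefers
  the largest threshold statistically tied with the profile maximum.
* **Stratum comparison** — a stratified bootstrap test of the ICC
  difference below versus above the cutoff
  (`bootstrap_icc_difference()`).
* **Calibration** — through-the-origin regression `CVP = β·FIVP` with
  uncentered R², and a summary of the above-cutoff FIVP − CVP bias
  (`fit_proportional_regression()`, `difference_summary()`).
* **Study design** — the expected lower confidence bound of a planned
  ICC study and the smallest n meeting a lower-bound requirement
  (`icc_lower_bound_at_n()`, `min_n_for_lower_bound()`).
* **Synthetic cohorts** — a changepoint-bias generator for paired
  pressures sharing a latent true value, with closed-form population
  ICCs and analytic calibration (`simulate_cohort()`, `expected_icc()`,
  `calibrate_noise_for_icc()`, `calibrate_offset_for_icc()`), standing
  in for unpublished patient data.

See the vignette (`vignettes/iap-stratified-agreement.Rmd`) for the
model, the calibration algebra and the design choices.

## Worked example

```r
library(iapagree)
sim <- simulate_cohort(cohort_params(n_sets = 120, seed = 1))
report <- run_full_analysis(sim$records,
                            analysis_config(n_boot = 500, seed = 1))
report
```

```
Paired venous pressure agreement analysis (120 sets)
Best IAP cutoff: 15 mmHg (rule: ci-band)
Below cutoff:  One-way ICC(1,1): 0.906  95% CI [0.857, 0.939]  (excellent)
  n = 78 sets, k = 2; MSB = 39.74, MSW = 1.958 mmHg^2
Above cutoff:  One-way ICC(1,1): 0.535  95% CI [0.282, 0.719]  (moderate)
  n = 42 sets, k = 2; MSB = 32.49, MSW = 9.841 mmHg^2
Bootstrap ICC difference: delta = 0.371 (below n=78 vs above n=42), p = 0.003992 (B = 500)
Calibration (below cutoff): CVP = 0.963 FIVP  (uncentered R^2 = 0.9717, n = 78, residual s.d. = 1.94 mmHg)
Bias (above cutoff):        FIVP - CVP: median 3.76 (range -0.26 to 9.13) mmHg; 98% strictly positive (n = 42)
```

Reading: concordance is excellent (ICC 0.91) in the 78 sets measured at
low intra-abdominal pressure and only moderate (ICC 0.54) above the
selected 15 mmHg cutoff; the difference is significant by the stratified
bootstrap (p ≈ 0.004). Where agreement holds, FIVP needs essentially no
recalibration (slope 0.96, uncentered R² 0.97); above the cutoff FIVP
overestimates CVP by a median of 3.8 mmHg, almost always in the positive
direction. The generator's true changepoint for this cohort was
14 mmHg, so the scan landed within 1 mmHg of it.

Measurement tables can also be read from CSV (`read_measurements()`,
long replicate-level or wide per-set format) and reports written as JSON
or TSV (`write_report_json()`, `write_profile_tsv()`).

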