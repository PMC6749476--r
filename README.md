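# ecgm — wearable-informed correction of CGM error during exercise

Continuous glucose monitors (CGM) lose accuracy during aerobic exercise:
a sensor with a resting MARD (mean absolute relative deviation against
laboratory plasma glucose) of ~13% can degrade past 17% while cycling,
which matters to anyone dosing insulin from the trace — people with type 1
diabetes, clinicians, and artificial-pancreas algorithms alike. Consumer
wearables (activity trackers, multi-sensor bands, chest straps) record
energy expenditure, heart rate, skin temperature and movement at the same
one-minute cadence, and those signals co-vary with the exercise-induced
error.

`ecgm` is an R package for building and evaluating a wearable-driven
correction of that error. The model is intentionally simple: with
`E_i(k) = CGM_i(k) − PG_i(k)` the per-sample estimation error of stream
*i*, the error is fit as a **zero-intercept** linear model on the
baseline-removed wearable signals,

    E = Θ · p,     Θ = [FHR, FST, FLV, FME, FCA, MHR, MTM, MGS, MST, MMO, PHR]

(each signal minus its per-trial resting-period median), and the enhanced
CGM is `eCGM = CGM − Ê`. Forcing the intercept to zero means the correction
acts only where the wearables depart from rest, leaving resting accuracy
untouched. The package implements the full workflow around that model:

* a **synthetic trial generator** (`generate_cohort()`) producing
  exercise-session cohorts whose CGM error obeys the model by construction
  — with configurable coefficients, noise, per-signal missingness and
  faulty-stream injection — since clinical datasets of this kind are not
  generally shareable;
* **ingest and QC** (`read_trial()`, `align_cgm()`, `pair_with_reference()`,
  `qc_filter()`): minute-grid alignment, CGM–reference pairing, discarding
  of streams with >30% faulty samples;
* **preprocessing** (`remove_baseline()`, `availability()`): per-trial
  rest-median baseline removal and signal-availability accounting;
* **four-criterion backwards input selection** (`select_inputs()`):
  availability (<70% discarded), redundancy (|r| ≥ 0.85 keeps the
  better-available / normalized member), exercise relevance (step counts
  are useless on a cycloergometer), and a cross-validated MARD elimination
  loop on common random partitions;
* **evaluation** (`crossvalidate()`, `mard()`, `glycemic_cv()`,
  `mard_significance()`): 20-repeat leave-nine-out cross-validation
  (18 fitting / 9 validation streams), MARD by period, glycemic CV, paired
  Wilcoxon significance;
* **clinical accuracy grading** (`clarke_zone()`, `parkes_zone()`,
  `iso_acceptable()`, `zone_summary()`): Clarke error grid, Parkes type-1
  consensus grid (published vertex table shipped in `inst/extdata/`), and
  the ISO 15197:2013 acceptance region;
* a deterministic **end-to-end pipeline** (`run_pipeline()`) with one seed,
  stage artifacts and a hash manifest.

## Worked example

```r
library(ecgm)

cfg <- synth_config(n_streams = 27, seed = 1)   # study-scale cohort
streams <- generate_cohort(cfg)
prepped <- lapply(streams, remove_baseline)
report <- crossvalidate(prepped, c("FME", "MTM"), seed = derive_seed(1, "cv"))
print(report)
#> <crossval_report: 20 repeats, model [FME, MTM]>
#>    period original enhanced p_value
#>  Exercise   18.01%   14.41% 0.00047
#>      Rest   12.17%   11.95% 0.32000
#>     Total   13.54%   12.53% 0.00074
#>        CV   17.95%   17.69% 0.09000
```

Read: on 27 synthetic streams the uncorrected sensor has 18.0% MARD during
the exercise period against 12.2% at rest. Correcting with the two-input
model — `FME` (Fitbit METs, normalized energy expenditure) and `MTM`
(wrist skin temperature) — brings the exercise error down to 14.4%
(p < 0.001 across validation streams), while the resting error and the
glycemic variability (CV) are statistically unchanged: the correction
removes exercise-specific error and nothing else. The same pairs can be
graded clinically:

```r
zs <- zone_summary(report$pairs, "clarke")
subset(zs, period == "exercise" & zone == "A")
#>   method   period source zone  pct   n
#> 1 clarke exercise    cgm    A 61.7 444
#> 6 clarke exercise   ecgm    A 73.6 530
```

i.e. the share of exercise-period pairs in Clarke zone A (clinically
accurate) rises from 61.7% to 73.6% after enhancement.

The scripted analysis in `analysis/01_simulate.R` …
`analysis/05_error_grids.R` runs the same workflow at full scale — 36
simulated streams, QC down to 27, the four-criterion elimination (arriving
at the two-input model `Θ = [FME, MTM]`), cross-validation and all three
error grids — writing its tables under `results/analysis/`.

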