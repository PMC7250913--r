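# neuronsurv

Longitudinal survival analysis of individual neurons followed by automated
two-channel time-lapse fluorescence microscopy.

In these experiments, primary neurons are transfected with a red-tagged
construct (e.g. a disease-associated protein variant) together with a green
transcriptional stress reporter, and the same fields are imaged every 24 h
for ~5 days. Each neuron yields a survival time — the last frame at which
it was observed alive — and a per-frame fluorescence trajectory. The
scientific question is whether the reporter level of a single neuron
predicts its subsequent risk of death, beyond the effect of the construct
it expresses.

`neuronsurv` provides the whole pipeline, validated end-to-end against
simulated ground truth:

* **Synthetic experiments** (`simulate_fates()`, `render_movie()`): death
  times drawn from a programmable proportional-hazards model
  `h(t) = h0(t) exp(beta_group + gamma * z(t))` with a Weibull or constant
  baseline, group effects, and a time-varying standardized reporter level
  `z(t)`; reporter trajectories with lognormal cell-to-cell dispersion and
  an optional pre-death surge; rendering as 16-bit two-channel TIFF stacks
  (Gaussian blobs, photobleaching, Poisson + read noise) with exact ground
  truth for every neuron.
* **Tracking** (`segment_frame()`, `link_tracks()`, `track_experiment()`):
  per-frame Otsu segmentation with watershed splitting, centroid linking
  with a no-re-acquisition death call, and background-subtracted red/green
  quantification on red-channel masks.
* **Statistics** (`nelson_aalen()`, `fit_cox()`, `schoenfeld_ph_test()`,
  `assign_quartiles()`, `quartile_hazard_model()`): Nelson–Aalen cumulative
  hazards; Cox models with well-level cluster-robust variance (with the
  standard `G/(G-1)` + `t` few-cluster correction) and plate-level
  stratification; Schoenfeld-residual proportional-hazards diagnostics;
  reporter normalization; and quartile-binned reporter-hazard models
  left-truncated at the reporter reference time.
* **Orchestration** (`run_pipeline()`, `render_report()`): a single
  YAML/JSON config drives simulate → track → analyze with CSV
  intermediates, a manifest, and summary figures.

## Worked example

Simulate two plates of a two-group experiment (control `Ch` vs
`G93ASOD1Ch` at a programmed hazard ratio of 1.5, with the reporter level
coupled to the hazard), then run the statistical pipeline on the ground
truth:

```r
library(neuronsurv)

design <- experiment_design(plates = 2, wells_per_plate = 4,
                            fields_per_well = 3, neurons_per_field = 12,
                            group_of_well = c("Ch", "Ch",
                                              "G93ASOD1Ch", "G93ASOD1Ch"))
hazard <- hazard_model(group_log_hr = c(Ch = 0, G93ASOD1Ch = log(1.5)),
                       reporter_log_hr = 0.27)
truth <- simulate_fates(design, hazard, seed = 11)
#> Ground truth: 288 neurons; 148 deaths, 140 censored at 120 h

rec <- build_survival_records(truth$fates, series = truth$trajectories,
                              end_of_followup = 120, reporter_times = 24)
head(nelson_aalen(rec), 4)
#>   group time n_risk n_event     cumhaz          var      ci_lo     ci_hi
#> 1    Ch   24    130       7 0.05384615 0.0004142012 0.02567029 0.1129480
#> 2    Ch   48    123      14 0.16766729 0.0013395763 0.10930472 0.2571922
#> 3    Ch   72    109      14 0.29610766 0.0025179283 0.21242392 0.4127583
#> 4    Ch   96     95      16 0.46452871 0.0042907815 0.35235712 0.6124097

fit_cox(rec)   # clustered by well, stratified by plate
#> Cox PH fit (breslow ties): 262 neurons, 122 events, 8 clusters, 2 strata
#>             term    hr ci_lo ci_hi     p
#>  groupG93ASOD1Ch 1.598  1.12  2.28 0.017

qa <- assign_quartiles(rec, "green_24h", reference_time = 24)
quartile_hazard_model(rec, qa, adjust_by_group = TRUE)
#> Reporter-quartile Cox model at 24 h (n = 262)
#>             term    hr ci_lo ci_hi      p   n
#>       quartileQ1 1.000    NA    NA     NA 262
#>       quartileQ2 1.475 0.979 2.223 0.0600 262
#>       quartileQ3 1.846 0.927 3.679 0.0740 262
#>       quartileQ4 3.094 1.869 5.123 0.0011 262
#>  groupG93ASOD1Ch 1.459 0.985 2.163 0.0570 262
```

Reading the output: the Nelson–Aalen table gives each group's cumulative
risk of death over follow-up with pointwise 95% CIs. The Cox fit reports
the toxic construct's hazard ratio (here 1.60 recovered against a
programmed 1.5) with a cluster-robust CI that accounts for neurons sharing
wells. The quartile model bins neurons by reporter level at 24 h and shows
the death risk rising from Q1 to Q4 (neurons enter the risk set at 24 h,
avoiding immortal-time bias); the Q4 estimate reflects the programmed
reporter–hazard coupling. The 26 neurons "dropped" in passing were alive
only on the first frame and carry no at-risk time on the study clock.

To run the same analysis from rendered images instead of ground truth:

```r
run_pipeline(list(
  seed = 1, out = "run1",
  simulate = list(
    design = list(plates = 1, wells_per_plate = 2, fields_per_well = 3,
                  neurons_per_field = 10, group_of_well = c("Ch", "G93ASOD1Ch")),
    hazard = list(group_log_hr = list(Ch = 0, G93ASOD1Ch = 0.405))),
  analyze = list(reporter_times = c(24, 48), adjust_group = TRUE)))
render_report("run1")
```

which writes TIFF movies, tracks them, and leaves `records.csv`,
`na_curves.csv`, `cox_fit.csv`, `quartile_model_*.csv`, `ph_test.csv`,
`manifest.json` and figures under `run1/`.

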