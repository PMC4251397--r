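# apwkit

Multi-parametric analysis of arterial pressure waveforms (APW) in R: from a
raw 1 kHz carotid pressure trace to per-subject cardiovascular-risk
classification.

## The problem

A single arterial pressure beat carries three prominent landmarks: the
systolic peak **SP** (left-ventricular ejection), the point of inflection
**Pi** (the reflected wave superimposing on the forward wave), and the
dicrotic wave **DW** (aortic valve closure). Clinically the most used
summary is the signed augmentation index

```
AIx(%) = ± (SP_a − Pi_a) / A × 100
```

positive when Pi arrives before SP (a "type A" pulse, the arterial
stiffness pattern) and negative when it arrives after (type C, healthy).
Single-index analysis fails whenever Pi is hard to locate, so this package
implements the multi-parametric alternative: per-beat arrival times and
amplitudes, six morphological ratios R1–R6 (e.g. R1 = SP_t/T,
R5 = |SP_a − Pi_a|, R6 = Pi_a/SP_a), beat-to-beat variability statistics
(RMSSD per fiducial coordinate, RMSE against the mean pulse, FWHM),
information-gain feature ranking with MDL discretization, four classifier
families (random forest, pruned decision tree, RIPPER-style rules,
discretized naive Bayes) under stratified 10-fold cross-validation, and
per-subject majority-vote predictions reported as class-A/class-B
percentages next to the AIx summary.

Because no recordings of this kind are publicly deposited, the package
ships a synthetic waveform generator calibrated to published cohort
statistics for a hypertensive group (SP_t 219.99 ± 51.03 ms, Pi_t
118.94 ± 39.95 ms, DW_t 313.52 ± 55.00 ms, AIx 9.57 ± 15.20 %), a healthy
group (144.12 ± 50.46, 200.46 ± 34.19, 291.84 ± 35.28 ms, −20.58 ±
20.03 %), and a young validation group (AIx 10.62 ± 7.86 %). Every
generated beat carries ground truth from an exhaustive oracle that shares
no code with the production detector. See the methods vignette
(`vignettes/apw-methods.Rmd`) for the generator model, the detector design
and their limitations.

## Worked example

```r
library(apwkit)

cohorts <- default_cohorts()                      # calibrated study groups
rec <- generate_recording(cohorts$groupI, "demo", n_pulses = 30, seed = 42)

corrected <- remove_baseline(rec$record)          # drift removal
pulses <- flag_anomalous(segment_pulses(corrected))
pulse <- normalize_pulse(pulses[[5]])

fid <- detect_fiducials(pulse)
print(fid)
#> <apw_fiducials> SP 271 ms / 0.991 | Pi 162 ms ( before_sp ) | DW 363 ms

compute_aix(fid$sp_amp, fid$pi_amp, fid$pi_order)
#> [1] 10.4
```

The generated truth for this beat was SP at 270 ms, Pi at 150 ms and a true
AIx of 10.3 %: the detector recovered the peak within 1 ms, classified the
beat as type A (Pi before SP, positive index) and the augmentation index
within 0.1 percentage points. `run_pipeline(pipeline_config(seed = 1))`
chains the whole analysis — simulation, preprocessing, detection, feature
tables (ARFF + CSV), information-gain ranking, cross-validation with ROC
points, and per-subject majority-vote predictions — writing every artifact
to disk stamped with the configuration hash.

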