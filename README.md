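# afwear

Atrial-fibrillation (AF) detection from wearable photoplethysmography (PPG)
inter-beat intervals (IBIs), for researchers evaluating rhythm-screening
algorithms on long ambulatory recordings. The package implements the full
analysis chain of a 24-hour inpatient AF-screening study — five-minute
windowing with an 80 % signal-quality gate and interpretable-time
accounting, nRMSSD threshold classification, an unsupervised
mutual-information representation learner with 1-nearest-neighbour and
supervised heads, and the diagnostic-accuracy reporting suite — plus a
calibrated synthetic cohort simulator, so every stage is testable without
access to clinical recordings.

## The methods in brief

**nRMSSD.** For each retained five-minute period,

```
nRMSSD = sqrt( mean( (IBI[i+1] - IBI[i])^2 ) ) / mean(IBI)
```

with successive differences taken only across retained, time-contiguous
beats (never across an excluded beat or dropout gap). The decision
threshold is calibrated by maximizing Youden's J (= Se + Sp − 1) on the ROC
of the first 80 % of patients by recruitment order, then applied unchanged
to the remaining 20 %.

**Mutual-information encoder.** Beats are encoded with their IBI value in
the coordinate block of their quality score (beats of different quality are
orthogonal), passed through a width-3 temporal convolution with masked mean
pooling, and projected to a unit-norm 64-d embedding. Training maximizes an
InfoNCE bound on the mutual information between the two halves of each
period around a random split point. Periods are then classified
unsupervised by 1-NN against labelled training embeddings, or by a small
supervised head on the frozen features, evaluated on random 80/10/10 splits
and ten-fold cross-validation.

**Simulator.** Sinus rhythm = slow sinusoidal RR modulation + jitter
(tight Poincaré cluster); AF = i.i.d. gamma renewal process, CV 0.22
(diffuse cloud); flutter = switching conduction ratios of a 250 ms atrial
cycle. Per-beat quality scores, per-patient log-normal frailty, dropout
bursts, a two-peak diurnal activity profile (16.1 % active blocks), and
three motion-artifact mechanisms (timing jitter, missed-pulse IBI doubling,
tracker-lock regularization) reproduce the cohort statistics the analysis
assumes. See the methods vignette (`vignettes/af-detection-methods.Rmd`)
for every default and its rationale.

## Worked example

```r
library(afwear)
run <- run_af_pipeline(sim_config(seed = 9))
run
#> af_run: 102 patients, 21825 gated periods
#>   interpretable time: 78.2% pooled (55.9% of patients >= 80%)
#>   nRMSSD threshold 0.2637 | test cohort: af_metrics: Se 97.7%, Sp 99.4%, PPV 98.8%, NPV 98.9%, AUC 0.999 (n=4488)
#>   1-NN latent (test split): af_metrics: Se 100.0%, Sp 99.8%, PPV 99.6%, NPV 100.0%, AUC 1.000 (n=2183)
#>   linear probe accuracy: 1.000
```

Reading the output: of the 102 simulated patients, 78.2 % of pooled
recording time passed the 80 % coverage gate (the "interpretable time");
the nRMSSD threshold learned on the training cohort was ≈ 0.26, and applied
to the held-out testing cohort it detected AF periods with 97.7 %
sensitivity and 99.4 % specificity. On the activity-stratified view
(`run$nrmssd$test$active`) the nRMSSD classifier degrades during physical
activity while the latent 1-NN classifier (`run$mi$knn$active`) does not —
the motion-artifact asymmetry the quality-orthogonal encoding is designed
to absorb. `run_report(run, "out/")` writes the deterministic JSON/CSV
report.

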