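# lcarousal

Analysis toolkit for multi-modal studies of **arousal-related memory
processing**: experiments that combine an emotional face–name memory task
with pulse-oximeter heart-beat recordings, serial salivary alpha-amylase
(sAA) samples, and BOLD time courses extracted from the locus coeruleus
(LC) and medial-temporal-lobe regions across task stages (baseline,
encoding, consolidation, recollection).

The package implements the complete non-imaging analysis chain for such a
design, for researchers who have extracted ROI time series and want the
behavioral, autonomic and spectral statistics end to end:

* **Behavioral scoring** under the equal-variance signal-detection model:
  `d' = z(H) − z(F)`, criterion `c = −(z(H)+z(F))/2`, likelihood-ratio
  response bias `β = exp(d'·c)` with `1/(2N)` extreme-rate correction;
  recollection rates corrected for response bias by across-subject
  residualization, and the adjusted emotional memory score `E/(E+N)`.
* **Pulse preprocessing**: adaptive beat cleaning (25–200 bpm bounds plus
  a 13% running-mean rule), gap flagging with a 10%-missing exclusion
  rule, cubic-spline HRV series (successive R-R differences on the TR
  grid), time-domain rMSSD, stage-wise ΔsAA, HRV-minima arousal events
  and double-gamma HRF regressors.
* **Spectral coupling**: Welch cross-spectra (Hamming tapers, 20%
  overlap, 90 bins on 0–0.5 Hz), magnitude-squared coherence
  `|P_AB|²/(P_AA·P_BB)`, four-quadrant phase lag (positive = first series
  leads), the cross-subject band of maximum coherence (bootstrap CI of
  the median per-subject peak), partial coherence from the inverse
  spectral matrix, and AR(1)-matched surrogate null distributions.
* **Association statistics**: repeated-measures correlation (ANCOVA
  formulation) with subject-level bootstrap CIs, random-intercept mixed
  models with Satterthwaite tests, Tukey-adjusted marginal stage
  contrasts, Johnson–Neyman regions of significance over frequency, and
  Benjamini–Hochberg FDR.
* **A synthetic-data generator** producing study-shaped cohorts with
  known ground truth (SDT parameters per valence, coupled BOLD–HRV series
  with controllable coherence magnitude and phase in a chosen band over
  AR(1) noise, beat timelines with controllable rMSSD and artifacts,
  stage-structured sAA), so the whole chain is testable without any
  participant data.

Everything is data-frame first: functions take tibbles and return tibbles,
fitted objects have `tidy()`/`glance()` methods and `autoplot()`
visualisations, and the pipeline composes with the pipe.

## Worked example

Simulate a small cohort with LC–HRV coupling of magnitude 0.7 at 0.2 Hz
(LC leading by π/2) and a +60 U/ml consolidation sAA effect, then run the
full chain:

```r
library(lcarousal)

cfg <- cohort_config(n_subjects = 8, series_length = 240, seed = 42)
study <- simulate_study(
  cfg,
  coupling_by_stage = setNames(rep(list(coupling_spec(target_msc = 0.7,
                                                      target_phase = pi/2)), 4),
                               cfg$stages),
  saa_effects = c(baseline = 0, encoding = 10, consolidation = 60,
                  recollection = 10))
report <- run_all(study, n_boot = 500, n_surrogates = 100)
report$band
#> <max_coh_band> median 0.2022 Hz, 95% CI [0.1910, 0.2108] (8 subjects, 500 bootstrap resamples)
tidy(report$rmcorr$saa_rmssd)
#> # A tibble: 1 × 5
#>   estimate    df p.value conf.low conf.high
#>      <dbl> <int>   <dbl>    <dbl>     <dbl>
#> 1   -0.294    23   0.153   -0.525     0.128
```

The recovered band of maximum coherence sits on the grid bin nearest the
generated 0.2 Hz coupling, with its bootstrap CI inside the
high-frequency HRV band. The repeated-measures correlation between ΔsAA
and rMSSD is the common within-subject association across the four task
stages (this cohort was generated without a built-in ΔsAA–rMSSD link, so
the estimate is compatible with zero). `make_report(report)` renders the
full bundle — behavioral summary table, stage measures, coherence band,
surrogate tests, associations — as Markdown, and `write_report()` writes
the TSV/JSON artifacts.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/lcpipeline simulate --config cfg.yaml --out study_dir
Rscript inst/scripts/lcpipeline run --data study_dir --out results_dir
```

## Documentation

The methods vignette (`vignettes/arousal-memory-pipeline.Rmd`) describes
the models and estimators, the synthetic-data generator and its ground
truth, the numerical choices, and known limitations.
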