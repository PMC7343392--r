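---
title: "Methods: autonomic-coupled memory analysis with lcarousal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: autonomic-coupled memory analysis with lcarousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The scientific setting

The locus coeruleus (LC) is the brainstem's principal norepinephrine source
and sits at the crossroads of arousal, autonomic control and memory.
Studies of arousal-related memory couple several very different data
streams: a recognition/recollection memory task with emotional and neutral
stimuli, pulse-oximeter heart-beat recordings (heart-rate variability, HRV,
indexes parasympathetic tone), serial salivary alpha-amylase samples (sAA,
a sympathetic/noradrenergic proxy), and BOLD time courses extracted from
small regions of interest (LC, a pontine reference, amygdala, hippocampus,
entorhinal cortex) across task stages: baseline rest, encoding,
consolidation rest, and recollection.

`lcarousal` implements the full non-imaging analysis chain for such a
design, plus a synthetic-data generator with known ground truth so that
every stage of the chain is testable end to end without access to any
participant data. Imaging preprocessing (registration, denoising, ICA,
voxelwise GLMs) is explicitly out of scope: the pipeline ingests
already-extracted ROI time series.

# Behavioral scoring

Recognition is scored under the equal-variance Gaussian signal-detection
model. With ceiling/floor-corrected hit rate $H$ and false-alarm rate $F$:

$$d' = z(H) - z(F), \qquad c = -\tfrac{1}{2}\,[z(H) + z(F)], \qquad
\beta = \exp(d'\,c),$$

where $z$ is the standard-normal quantile and $\beta$ is the
likelihood-ratio response bias. Rates of exactly 0 or 1 are replaced by
$1/(2N)$ and $1 - 1/(2N)$ before the transform (the deterministic
correction with the longest lineage; a log-linear alternative,
$(k+0.5)/(N+1)$, is available behind the `correction` flag). The identity
$\beta = \exp(d'c)$ holds to machine precision by construction and is
asserted property-style in the tests.

Recollection (correct name retrieval) is scored two ways, matching
standard reporting: raw (correct names / all old faces) and conditional on
recognition (correct names / recognized old faces). Because emotional
stimuli typically attract a more liberal recognition criterion, the
conditional recollection rate is corrected for response bias: an
across-subject OLS regression of the rate on $\beta$, fitted separately
per valence, whose residuals are re-centered at the sample mean so
corrected rates stay on the percentage scale. Mean re-centering (rather
than median) was chosen because OLS residuals are exactly mean-zero, which
makes the re-centering an identity on the fitted sample. With zero bias
variance the slope is undefined and the rates are returned unchanged with
a warning. The per-subject emotional memory score is
$E/(E+N)$ on the corrected rates; 0.5 is valence-neutral, and the score is
flagged missing when $E+N \le 0$.

Group contrasts use the Wilcoxon signed-rank test with the normal
approximation, tie correction and a 0.5 continuity correction, reporting
the signed $Z$; the implementation is cross-checked against
`stats::wilcox.test` p-values on tie-free data in the tests. Note that for
fully tied differences (e.g. a constant shift) the tie-corrected $Z$
exceeds the tie-free closed form — both are asserted in the tests.

# Pulse preprocessing and autonomic measures

Beat cleaning applies two rules to the instantaneous rate implied by each
inter-beat interval, measured against the last accepted beat: absolute
physiological bounds (25–200 bpm) and an adaptive rule rejecting rates
deviating more than 13% (configurable) from the running mean of the last
10 accepted intervals. The two rejection directions are handled
asymmetrically, which is the one place we refine the classical adaptive
filter: an implausibly *fast* interval marks a spurious beat, which is
deleted while the anchor stays at the last accepted beat; an implausibly
*slow* interval marks missing beats, so the segment is flagged as a gap
but the terminating beat is kept as the new anchor. Deleting the beat
after a gap would only lengthen the gap and cascade into rejecting the
entire remainder of the recording. This makes cleaning idempotent
(verified in the tests) and gives the 10%-missing exclusion rule a
well-defined input: a stage is unusable when more than 10% of its grid
time points fall in gaps or outside beat coverage.

The HRV series is the sequence of successive R-R interval differences
(ms), cubic-spline interpolated onto the equidistant acquisition grid
(the TR). rMSSD — $\sqrt{\operatorname{mean}(\Delta RR^2)}$ — is computed
on the raw accepted intervals, never on the interpolated series, because
interpolation smooths exactly the successive differences rMSSD measures;
gaps are never bridged. For i.i.d. Gaussian intervals with standard
deviation $\sigma$, rMSSD converges to $\sigma\sqrt{2}$, which anchors the
generator's ground truth and the tests.

sAA follows the seven-swab session schedule (before the bore, before
baseline, before/after encoding, before/after recollection, +30 min).
$\Delta$sAA per stage is end-minus-beginning under the pairing: baseline =
(pre-baseline → pre-encoding), encoding = (pre → post encoding),
consolidation = (post-encoding → pre-recollection), recollection = (pre →
post recollection). The pairing is configurable because the assignment of
the seven samples to four stages admits alternatives; this one uses each
consecutive pair exactly once. Missing endpoints propagate to missing
deltas — never zero.

Arousal events for fMRI regressors are local HRV minima over a centered
15 s rolling window (strict minimum; ties flag the earliest sample), and
the event regressor convolves unit impulses with a double-gamma
haemodynamic response function. The gamma components are parameterised by
their peak times — response peaking at 6 s, undershoot at 16 s, amplitude
ratio 6 — i.e. shape $= \text{delay}/\text{dispersion} + 1$ at rate
$1/\text{dispersion}$, so the response mode falls at exactly 6 s.

# Spectral coherence

Cross-spectra are estimated by Welch averaging of Hamming-tapered,
mean-detrended segments with 20% overlap. The analysis grid has 90
one-sided bins spanning 0–0.5 Hz, which fixes the segment length at
$2 \times (90-1) = 178$ samples at the working rate. A 0–0.5 Hz grid
requires a Nyquist frequency of 0.5 Hz, which BOLD sampled at TR = 2 s
(Nyquist 0.25 Hz) cannot supply; the pipeline therefore resamples series
to a 1 Hz working grid by cubic splines before estimation (both grid and
rate are configurable). Two consequences are documented and handled:

* content above the native Nyquist consists of interpolation images of
  the sub-Nyquist signal. Because the imaged signal is *shared* between
  channels, those bins show spurious coherence (the coupling band's mirror
  about 0.25 Hz is clearly visible in synthetic data). The peak search for
  the band of maximum coherence therefore stops at the native Nyquist;
* an 8-minute stage yields $K = 3$ Welch windows, so single-bin coherence
  estimates are noisy and biased upward (the no-coherence expectation of
  the magnitude-squared coherence is approximately $1/K$, verified by
  Monte Carlo at $K = 8$). All inference runs against matched surrogate
  nulls rather than nominal distributions.

Magnitude-squared coherence and phase use the standard conventions

$$C_{AB}(f) = \frac{|P_{AB}(f)|^2}{P_{AA}(f)\,P_{BB}(f)} \in [0, 1],
\qquad \theta_{AB}(f) = \operatorname{atan2}\!\big(\mathrm{Im}\,P_{AB},
\ \mathrm{Re}\,P_{AB}\big),$$

with the sign convention that positive phase means the first series
leads. Phase estimates at bins whose coherence falls below 0.1 are flagged
unreliable. MSC is symmetric in its arguments, phase antisymmetric, and
both are invariant to positive rescaling of either series — all asserted
as properties.

The cross-subject frequency band of interest is the bootstrap percentile
95% CI of the median of per-subject argmax frequencies of MSC (ties to the
lowest frequency; 5000 resamples, seeded). By default the pipeline
restricts the peak search to the HF-HRV band (0.15–0.4 Hz, the
conventional parasympathetic band) intersected with the native Nyquist
range: a parasympathetic coupling peak is by definition sought there, and
the restriction keeps single-stage peak estimates from being dragged by
noise excursions elsewhere on the grid. Per-subject, per-stage
point estimates are the median MSC (and circular median phase) over bins
inside the band.

Significance of band coherence is assessed against AR(1)-matched
surrogates: a lag-1 Yule–Walker fit per series, fresh white noise driven
through the fitted coefficient, variance-matched, and the band-median MSC
recomputed per surrogate pair (at least 100 pairs). The observed
per-subject band medians are compared to their subject-matched null
medians with the signed-rank test. The null's type-I error is calibrated
by simulation in the test suite (1000 replicates at $\alpha = 0.05$,
acceptance region 0.03–0.07).

Partial coherence between two series given a conditioning set is computed
from the inverse of the full cross-spectral matrix per bin,
$|G_{12}|^2/(G_{11}G_{22})$ with $G = P^{-1}$; with an empty conditioning
set this reduces *exactly* to ordinary MSC (a property test), and
near-singular bins are ridge-regularised with a warning (with $K$ windows
a spectral matrix of more than $K$ series is necessarily rank-deficient).
The surrogate-null construction extends to triples for testing partial
coherences.

# Association statistics

The repeated-measures correlation $r_{rm}$ is the common within-subject
association after removing subject means, computed by the ANCOVA
formulation (`y ~ subject + x`): $r_{rm} = \operatorname{sign}(b)\,
\sqrt{SS_x / (SS_x + SS_e)}$ with $df = n_{obs} - n_{subj} - 1$. The
p-value comes from the F test of the common slope; the 95% CI is a
subject-level percentile bootstrap (5000 resamples by default; degenerate
resamples with fewer than two usable subjects are redrawn). The
implementation agrees with the independently published `pingouin`
reference to $10^{-10}$ and with the subject-demeaning residual route to
$10^{-12}$ in the tests.

Stage models are random-intercept linear mixed models fitted by maximum
likelihood, with Satterthwaite degrees of freedom for coefficient tests;
the stage factor uses treatment coding with baseline as the reference
level, and all pairwise stage contrasts are reported from estimated
marginal means with Tukey (studentized-range) adjustment so any coding
convention can be matched against them. Singular random-effect fits fall
back to OLS with a warning. The coherence-by-stage model treats frequency
as a continuous fixed effect (bin centers), which is what a simple-slopes
analysis requires. Regions of significant moderation are Johnson–Neyman
boundaries: the conditional stage difference $\delta(f) = a_0 + a_1 f$ is
significant where $\delta(f)^2 > t^2\,\mathrm{Var}[\delta(f)]$, a
quadratic whose real roots (intersected with the observed frequency range)
bound the region; the closed form is verified against a dense grid scan of
pointwise tests to one grid step. Families of correlations are adjusted
with Benjamini–Hochberg FDR.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions under which the package validates itself.

**Behavior.** Latent familiarity is $N(d', 1)$ for old and $N(0, 1)$ for
new items with decision threshold $k = c + d'/2$, reproducing
$H = \Phi(d'/2 - c)$ and $F = \Phi(-d'/2 - c)$; given a hit the correct
name is drawn with a per-valence recollection probability. Defaults (45+45
old, 23+22 new; $d'$ 0.83/1.18, $c$ 0.33/0.51 emotional/neutral;
recollection 0.50/0.45) mirror a young-adult cohort on this paradigm,
including the emotional false-alarm inflation that motivates the bias
correction.

**Coupled series.** Both channels share a band-limited latent built by
zero-phase frequency-domain masking of white noise; the second channel's
copy is phase-shifted exactly in the frequency domain, so the target
phase applies without group-delay distortion. Independent AR(1) noise
(default $\phi = 0.3$, unit variance) is added per channel. The latent
spectrum is shaped $\propto \sqrt{G(f)\,N(f)}$ — $N$ the AR(1) noise PSD,
$G$ the band-shape gain — giving theoretical coherence
$\big(a^2 S / (a^2 S + N)\big)^2$ with a *flat* or analytically *peaked*
profile; the mixing weight solves
$a^2 = V \rho/(1-\rho)$, $\rho = \sqrt{\text{target MSC}}$, $V$ the
band-integral of $G N$. Without the $\sqrt{N}$ weighting the AR(1) noise
tilts in-band coherence toward the upper band edge and biases peak
recovery. The default shape is peaked (Gaussian gain, sd =
band width / 4, truncated at the band edges): physiological coupling
concentrates at a characteristic frequency, and a flat profile would make
the per-subject argmax uniform over the band, leaving "the" peak frequency
undefined at the grid's resolution. The flat shape remains available for
analytic calibration of the coherence magnitude, and both shapes are
exercised in the tests.

**Beats.** Clean R-R intervals are i.i.d. Gaussian (ground-truth rMSSD
$\sigma\sqrt{2}$); artifacts are spurious beats inserted a quarter of the
way into a fraction of intervals (instantaneous rate ≈ 4× the rhythm), so
default cleaning recovers the clean timeline exactly. To couple the
heart-beat stream to the LC channel, the coupled partner $y$ is imprinted
as $RR_k = \overline{RR} + s\cdot\sum_{i\le k} y(t_i)$: the successive
R-R differences then equal $s\,y$ at the beat times, and the
pipeline-derived HRV series inherits the target coherence (MSC is
scale-invariant). $y$ is high-passed below the coupling band first,
because cumulative summation amplifies low frequencies as $1/(2\pi f)$
and residual noise power near DC would random-walk the R-R baseline.

**sAA.** Log-normal multiplicative noise (sd 0.1 on the log scale) around
a deterministic stage path whose increments are the per-stage effects;
log-normal because sAA is non-negative and right-skewed.

**Seeding.** One cohort seed expands into per-subject, per-stage,
per-stream child seeds through a label-hash kept below $2^{31}-1$, so any
subset of a study regenerates reproducibly on its own.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: respiratory confounds and respiratory sinus
arrhythmia, motion and scanner artifacts, non-stationary coupling within
a stage, heavy-tailed R-R distributions, subject-level heterogeneity in
coupling frequency, and any spatial structure (no images are synthesized).
Recovery results on synthetic data demonstrate the correctness of the
estimators under the stated model, not robustness to everything real
recordings contain.

# Problem sizes and numerical choices

Validation uses cohorts of 20 subjects with four 8-minute stages at
TR = 2 s (240 samples per stage; 480 working-grid samples, $K = 3$ Welch
windows), 100 surrogates per null, 1000 replicates for type-I calibration,
and 1000–5000 bootstrap resamples — sizes chosen to match the study design
the package targets while keeping the full test suite comfortably
desk-scale. Other numerical choices: MSC clipped to $[0,1]$ against
rounding; AR(1) coefficients clipped into $(-1,1)$ with a warning;
ridge $10^{-8}\cdot\overline{\mathrm{diag}}$ on singular spectral bins;
argmax ties to the lowest frequency; circular median phase as the
observed angle minimizing summed circular distance; all bootstrap and
surrogate draws seeded.

# Known limitations

* With $K = 3$ windows, single-subject, single-stage band peaks carry
  roughly one-frequency-bin sampling scatter; cross-subject medians (and
  pooling stages when their coupling is exchangeable) are the reliable
  quantities.
* The working-grid upsampling deliberately reports bins up to 0.5 Hz for
  compatibility with the fixed 90-bin convention, but frequencies above
  the native Nyquist carry no physiological information and are excluded
  from peak searches.
* The bias correction is an across-subject linear residualization; it
  removes the linear bias component only.
* `rmcorr` assumes a common within-subject slope; heterogeneous slopes
  are averaged, not modeled.
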