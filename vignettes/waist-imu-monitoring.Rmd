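---
title: "Methods: waist-worn accelerometry processing for Parkinson's disease monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: waist-worn accelerometry processing for Parkinson's disease monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdwear)
```

## The problem

Motor fluctuations in Parkinson's disease (PD) — freezing of gait (FoG),
bradykinetic gait, dyskinesia and the ON/OFF medication cycle — are episodic
and hard to capture in a clinic visit. A waist-worn inertial monitor
addresses this by recording triaxial acceleration continuously and running a
cascade of light-weight classifiers on-device, so that symptoms can be
time-stamped at home and, where appropriate, trigger rhythmic auditory
stimulation. `pdwear` implements that complete processing stack at desk
scale: the binary acquisition format, the multi-rate detection cascade, a
synthetic signal generator that stands in for patient recordings, the
episodic evaluation metrics, and the storage/memory budget arithmetic that
governs such a device.

## The processing cascade

Processing happens at four temporal levels:

1. **Sample level (40 Hz).** Each incoming sample is low-pass filtered with
   a 2nd-order Butterworth filter applied as the direct-form recursion
   $x'_i = \sum_{j=1}^{3} b_j x_{i-j+1} - \sum_{j=1}^{2} a_j x'_{i-j}$.
   Capture-mode sessions may be recorded at 50 Hz; the analysis cascade
   declares 40 Hz and the pipeline refuses mismatched rates rather than
   silently resampling.
2. **Window level (every 1.6 s).** Windows are 3.2 s long (N = 128 samples)
   with 50% overlap. Per window the features are per-axis population
   moments (mean, standard deviation, range, skewness, kurtosis), the signal
   magnitude area, pairwise Pearson correlations, and short-time Fourier
   band energies $\sum_h |X_h|^2$ over half-open bands $(f_{lo}, f_{hi}]$,
   plus band ratios and total non-DC power. Two RBF-SVM classifiers
   (walking yes/no, FoG yes/no) and a small dyskinesia decision tree run on
   the feature vector; walking windows additionally get a fluidity score
   and a cadence estimate.
3. **Minute level.** A minute is evaluated only if it reaches a quorum of
   gait windows (default 10 of ~37); it is bradykinetic when mean fluidity
   over its gait windows falls below the patient threshold $\theta_p$, and
   dyskinetic when at least half of its non-gait windows carry the
   dyskinesia label.
4. **Ten-minute level.** A fixed decision rule over the block's valid
   minutes yields ON, OFF or undetermined. FoG output never enters this
   rule.

The RBF-SVM decision function is
$f(x) = \mathrm{sign}\big(\sum_{i=1}^{l} \alpha_i y_i
e^{-\lVert x_i - x\rVert^2 / 2\sigma^2} + b\big)$, evaluated on features
z-scored with training-set statistics stored inside the model file. An
exact zero margin maps to the negative class: on a tie no symptom is
flagged, the conservative choice for a system that drives an actuation
channel. Training wraps libsvm; the extracted support vectors, weights and
bias are re-evaluated by the package's own decision function, which the
tests hold to within $10^{-6}$ of the trainer's decision values.

## Conventions and tunable parameters

* **Spectral indexing.** The device convention indexes harmonics
  $h = 1\ldots N$ with DC at $h = N$; internally the standard
  $k = 0\ldots N-1$ transform is computed and `harmonic_frequency()` maps
  between them ($f(h) = h \cdot \mathrm{rate}/N$ for $h \le N/2$).
* **Band dictionary.** Only the postural-transition band (0, 0.68] Hz is a
  printed constant. The locomotor (0.68, 3], freeze (3, 8] and dyskinetic
  (1, 4] bands are configurable defaults taken from the freeze-index
  literature and are flagged as such.
* **Filter cutoff.** The deployed filter's cutoff is not published; the
  default is 15 Hz at 40 Hz sampling, preserving the stated band of
  interest for walking (up to 20 Hz) while attenuating near-Nyquist noise.
  Exposed in `pipeline_config()`.
* **Moment denominators.** Window features use population (1/N) moments,
  matching the on-device formulas; the cohort summary uses sample (n−1)
  moments, which is what reproduces the published "mean ± sd" baseline
  values. Displayed dispersions follow the published truncation convention
  (e.g. an age dispersion of 6.2595 is printed 6.259); `trunc_dec()`
  implements it.
* **Fluidity sign.** The fluidity score is the fraction of non-DC power
  within ±0.5 Hz of the dominant locomotor harmonic: *lower* is less fluid.
  A test is bradykinetic when its mean score is *below* $\theta_p$. (The
  equivalent published description uses a severity index that *rises* with
  bradykinesia; only the sign convention differs.)
* **Cadence.** The waist vertical axis oscillates once per step, so the
  dominant locomotor peak sits at the step frequency and cadence is
  $60 f_{peak}$ steps/min (two steps per stride cycle). The peak is refined
  below the 0.3125 Hz bin width by quadratic interpolation on
  log-magnitude, and is rejected (cadence undefined) when it carries less
  than 10% of non-DC power. Step length and velocity are inverted-pendulum
  surrogates from the peak amplitude, reported for completeness and
  excluded from any accuracy claim.
* **Threshold personalisation.** The published system personalises
  $\theta_p$ with a regression model trained on three days of home data;
  `calibrate_brady_threshold()` substitutes the documented midpoint-of-
  condition-means rule behind the same interface, which is pluggable.
* **Degenerate windows.** A zero-variance block returns correlation,
  skewness and kurtosis 0 rather than an error; a feature-vector band ratio
  with an empty denominator band is 0 (the bare `band_ratio()` returns the
  `Inf` sentinel). A still window is symptom-irrelevant either way.

## The binary frame format

One acquisition record packs three triaxial accelerometers, gyroscope,
magnetometer, barometer, four temperatures, battery state, six real-time
clock registers and a sample counter — 94 payload bytes, zero-padded to a
128-byte frame. The published field list fixes the byte widths but not the
encodings or endianness; this implementation chooses little-endian
throughout (the convention of the Cortex-M4 class microcontroller such
devices use), IEEE-754 single precision for sensor channels (4 bytes/axis
matches the printed 12-byte triaxial budget), six unsigned bytes for the
clock (year offset from 2000) and a 4-byte unsigned counter. Session files
add a fixed 16-byte header (magic, version, rate, layout checksum, frame
size); counter gaps on read are reported as warnings, never repaired. At
the capture rate of 50 Hz this format needs 552.96 MB/day (decimal
megabytes — the unit convention that reproduces the printed figure).

## The synthetic-data generator

No recordings of the original cohort are deposited, so the simulator plays
the gold-standard role: it generates the signal regimes the detectors
assume, with ground-truth episode labels.

* **Gait**: 1 G gravity plus three harmonics of the step frequency
  (default 1.9 Hz; amplitudes 0.35/0.15/0.05 G vertical, scaled 0.45/0.3 on
  the horizontal axes) plus white noise (sd 0.03 G). Vertical gait std
  lands near 0.27 G, typical of waist recordings.
* **Freezing**: locomotor amplitudes attenuated to 20%, plus a trembling
  component (0.25 G) at a frequency drawn from the 3–8 Hz freeze band.
* **Bradykinetic gait**: step frequency and amplitude scaled by patient
  effect factors (defaults 0.6, drawn 0.5–0.8 per simulated patient),
  *plus* slow amplitude modulation and extra broadband noise. The last two
  matter: amplitude scaling alone barely moves a spectral-concentration
  score, whereas the reduced rhythmicity that clinically characterises
  bradykinetic gait spreads the locomotor peak, which is exactly what the
  fluidity score measures.
* **Dyskinesia**: irregular choreic oscillation, two sinusoids drawn from
  1–3 Hz on all axes.
* **Posture transitions**: a smooth gravity reorientation (0.4 rad) over
  the segment.

The elicitation protocol script chains stand-up, a 20 m walk, two turns, a
narrow-space passage and sit-down; freezes are inserted with probability
equal to the freezing propensity in the narrow passage and half that per
turn. A window used for training takes the label covering the majority of
its span.

What the simulator does **not** emulate: biomechanically detailed gait,
sensor saturation and drift, gyroscope/magnetometer/barometer content
(zero-filled in frames), or the enormous behavioural variety of real homes.
Passing the synthetic end-to-end acceptance therefore shows the *software
chain* is correct and well-calibrated on signals with the assumed spectral
structure — it does not re-establish the published clinical accuracy, which
was measured on real patients and is not recomputable without their data.

## Batch ≡ streaming

The published device computes per-sample work in interrupt handlers under a
priority scheme. The software contract replacing that here is equivalence:
feeding a stream one sample at a time through `stream_step()` yields
outputs bit-identical to `run_pipeline()`, and the streaming state is a
plain serialisable value, so a checkpointed run resumes exactly. Both
paths share one window-level processor; the filter recursion carries state
across chunks. Minute m owns the windows whose start sample lies in
[60m·rate, 60(m+1)·rate) and is emitted once the stream passes its end; a
freezing episode's events span [first flagged window start, last flagged
window start + stride], a convention that keeps the event log
timestamp-monotone under 50% overlap.

## Evaluation

Episodic sensitivity counts an annotated episode as detected when at least
one flagged window overlaps it; specificity is window-based over windows
that overlap no episode. From the published episode counts (87 detected of
106) the metric prints 82.08%. The published window specificity (97.19%)
is not recomputable from printed counts and is not claimed. The packaged
12-patient baseline table reproduces every printed cohort summary (age
65.5 ± 6.259; UPDRS III 26.75 ± 10.98 in the printed ON column and
14.5 ± 10.88 in the OFF column; Hoehn & Yahr 2.95 ± 0.14). Note the
published prose swaps the ON/OFF labels of the two UPDRS values relative
to the printed table; the fixture follows the table's column labels and
the discrepancy is documented rather than resolved.

The scaled-down end-to-end study (`end_to_end_eval()`) trains the gait and
FoG classifiers on 20 seeded synthetic sessions (plus bradykinetic and
daily-living sessions so both walking variants and non-walking activity are
represented), evaluates FoG episodically on 10 held-out sessions, and runs
the per-test bradykinesia evaluation on 20 simulated patients (two
calibration sessions per medication condition, one held-out test each).
These problem sizes keep the whole study under a minute on one CPU while
leaving dozens of episodes and patients in play; under the default
conditions the synthetic operating points sit at or near 100%, comfortably
above the acceptance floor (episodic sensitivity ≥ 0.80, window
specificity ≥ 0.90, per-test bradykinesia sensitivity 1.0 / specificity
≥ 0.9) that mirrors the published ballpark.

## Known limitations

* The deployed classifier constants (211 support vectors × 27 features) are
  not published; only their memory arithmetic is reproducible, and the
  default feature set is a documented reconstruction, not a claim of
  equality with the deployed 55-feature list.
* The support-vector reduction step used on-device (separable case
  approximation) is out of scope; models here keep all support vectors.
* Battery autonomy figures are estimates of measured hardware quantities;
  `autonomy_hours()` reports the arithmetic but the published day counts
  embed a measured consumption profile and are not asserted as exact.
* Gait parameter surrogates (step length/velocity) are deliberately simple
  and excluded from acceptance claims.
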