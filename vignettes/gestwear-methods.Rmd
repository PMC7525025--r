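---
title: "Activity and gesture outcome measures from wrist actigraphy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity and gesture outcome measures from wrist actigraphy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Negative symptoms of schizophrenia split into two dimensions: avolition
(apathy, amotivation, asociality) and diminished expression (flat affect,
poverty of speech, reduced gesturing). Both are hard to rate reliably in an
interview, which weakens signal detection in trials. A wrist-worn
accelerometer recording continuously at 20 Hz offers an objective,
longitudinal alternative: how much a patient moves about (ambulatory
activity, an avolition-adjacent measure) and how much they gesture while
otherwise still (an expression-adjacent measure).

`gestwear` implements that measurement pipeline end to end:

1. **Activity recognition** — classify fixed-length windows of the tri-axial
   signal into eight fine activities, mapped onto the binary dichotomy
   *ambulatory* = {walking, climbing stairs, cycling, jogging} versus
   *stationary* = {sitting, standing, lying down, hand work}.
2. **Gesture detection** — within stationary time, find epochs where the 1-s
   moving standard deviation of the acceleration magnitude exceeds 0.01 g.
3. **Feature aggregation** — per patient: activity-time ratio, median daily
   gesture count, aggregate gesture power, monitoring ratio.
4. **Clinical linkage** — Spearman correlations of those features (plus an
   effort-choice task score) against clinical scores (BNSS total, BNSS
   apathy index, BNSS diminished expression, PANSS NSFS and PSFS).

Because trial-grade actigraphy with clinical annotations is private, the
package ships a seeded synthetic-cohort generator that plays the role of the
data: every stage of the pipeline is exercised and tested against planted
ground truth.

## The gesture detector

For samples $a_t = (a_x, a_y, a_z)$ in g, the magnitude is
$m_t = \lVert a_t \rVert_2$, which hovers near 1 g at rest (gravity) and is
invariant to how the device happens to be rotated on the wrist. Over each
1-s window (20 samples) we compute the population SD (denominator $n$;
the threshold is a heuristic, and at $n = 20$ the $n$ vs $n-1$ choice moves
the SD by under 3%, but fixing it makes results reproducible). A window is
*eligible* when

* every sample in it is labelled stationary by the activity classifier, and
* its moving SD strictly exceeds 0.01 g (the idle/non-idle separatrix:
  below it a wrist is idle with ~99% probability).

Windows slide per sample (the finest resolution; the stride is
configurable). Eligible windows whose **start times** differ by less than
1 s are merged into one event. Two conventions needed fixing where the rule
is under-determined:

* *Gap measurement.* With per-sample stride, eligible windows on either
  side of a short sub-threshold lull overlap in time, so an end-to-start
  gap definition would merge everything; start-to-start separation gives
  the intended behaviour (bursts 0.5 s apart merge, bursts 1.5 s apart
  do not). A merge never bridges a window that fails the *stationarity*
  condition or a wear gap — events can therefore never contain ambulatory
  samples.
* *Event boundaries.* A moving-window statistic is naturally indexed at its
  centre. Reporting the span from the first to the last eligible window
  *centre* keeps boundaries within about half a window of the underlying
  burst; spanning full windows instead would pad every event by up to one
  second per side and make short (sub-2 s) gestures irrecoverable at any
  reasonable overlap criterion.

Per event, **gesture power** is $\sum_t (m_t - \bar m)^2$ over the event's
samples, where $\bar m$ is the within-event mean — i.e. $n$ times the
population variance, in g². **Gesture count** is the number of events per
day, a day being a half-open 24-h block from the study origin (the CSV
dialect carries no timezone, so civil-time days are out of reach); events
belong to the day containing their start.

## Activity recognition

The paper-scale approach trains a 9-layer convolutional recurrent network on
two public annotated wrist datasets (nine subjects each). What matters
downstream, though, is only the binary ambulatory/stationary separation, and
that is achievable with a deterministic baseline that runs on a CPU in
seconds: windows of 5 s (non-overlapping by default; the window length is a
package decision — the source method does not state one), 31 handcrafted
features per window (per axis and magnitude: mean, SD and log-SD, dominant
frequency and spectral power in the 0.5–5 Hz gait band and its log, the
band's peak-concentration ratio; plus the three between-axis correlations),
and a ridge-regularized multinomial linear model (`glmnet`). Movement
intensity spans orders of magnitude, hence the log features; periodic gait
concentrates band power in one frequency bin, hence the peak ratio — these
make the binary boundary essentially linear. A `conv_recurrent` classifier
kind is reserved in the interface but not shipped.

Evaluation follows the subject-wise protocol: per source, one held-out
subject for validation (used only to pick the ridge penalty) and one for
final testing; with 9 + 9 subjects that is the 14/2/2 split. Predicted
window labels are bridged to samples by majority vote over covering windows
with an earliest-window tie-break, which gives the sample-resolution
stationarity the gesture detector needs.

## Per-patient features

* **Activity-time ratio** — time labelled with a gait-involving activity
  divided by total *monitored* (covered) time; unclassified covered time
  stays in the denominator.
* **Monitoring ratio** — covered hours over enrolled hours. Coverage is the
  union of per-sample intervals, bridging inter-sample spacings up to twice
  the nominal period; wear detection is not defined by the source method, so
  the package makes the rule explicit and threshold-based.
* **Median daily gesture count** — median over *qualifying* days (≥ 8 h
  wear; without a valid-day rule, low-wear days bias counts downward; the
  source method states none, so 8 h is a package default, configurable).
  Even day counts take the mean of the two middle values. No qualifying day
  yields a missing value, never zero.
* **Aggregate gesture power** — median of per-day medians of per-event
  power, mirroring the "median daily" phrasing of the count; the original
  aggregation is unstated, and a mean variant is available.

The effort-choice task score is the percentage of high-effort choices among
trials offering 5 or 7 points at 100% reward probability (trials at 50%
probability or 3 points never enter the denominator); cumulated points
convert to a bonus at $1 per completed set of 20.

## The synthetic cohort

Two generators cover two needs.

**Signal level** (`simulate_schedule()` + `simulate_recording()`): days are
built from minutes-scale activity bouts (night-time lying, daytime mixtures,
explicit `non_wear` gaps steering the monitoring ratio toward 0.74, the wear
level typical of multi-week outpatient actigraphy). Stationary states emit
gravity plus Gaussian noise (SD 0.004 g, below threshold); hand work emits
sustained supra-threshold noise (0.05 g) — deliberately, mirroring the known
contamination of gesture detection by instrumental hand activity; gait
states emit a sinusoid plus one harmonic (state-specific cadence and
amplitude) plus noise. Gesture bursts are a Poisson process over quiet
stationary time with Uniform(0.5, 5) s durations — spanning sub-window to
multi-window events so the gap-merge rule is exercised — amplitude SD
0.05 g by default, and a 3 s minimum separation (closer planted events
would be indistinguishable from one gesture at 1-s window resolution). This
is the simplest model under which the 0.01 g separatrix is meaningful; it
does not attempt realistic biomechanics, device noise spectra, or the
temperature/light channels of real devices, so passing tests demonstrate
correctness of the *rules*, not field performance.

**Day level** (`simulate_cohort()`): the correlation stage needs per-patient
features for tens of patients over weeks, for which raw 20 Hz signal adds
runtime but no information. Patients draw latent traits from a Gaussian
copula built as a two-factor loading model — a severity factor behind the
clinical scores and a motivation factor behind activity and effort choice.
The factor construction is positive semi-definite by design; requested rank
couplings convert to latent Pearson correlations via
$\rho_P = 2\sin(\pi \rho_S / 6)$ and are planted exactly at the latent level
(targets needing a loading above 1 are rejected as infeasible). Defaults
mirror the signs and magnitudes a clinical cohort shows: gesture rate vs
BNSS total −0.44, gesture power vs diminished expression −0.42, activity vs
high-effort choice 0.58. Latents map monotonically to observables: lognormal
gesture rates (median 6/h) and per-event power scales, Beta ambulatory
fractions (mean 0.12), Beta-ranged integer scores centred on published
cohort means (BNSS total 36 ± 11.5, PANSS NSFS 23 ± 3.5, PSFS 19.2 ± 4.8),
and a logistic high-effort probability. Daily tables then add realization
noise: wear around the patient's monitoring ratio, Poisson gesture counts
over stationary hours, lognormal event powers. Feature-level correlations
are therefore slightly attenuated relative to the planted latent coupling
(by roughly 0.02–0.05 at these settings) — exactly as a real pipeline
attenuates a true association through measurement noise.

## Statistics

`spearman_test()` ranks with average ties. For n ≤ 7 the two-sided p-value
is exact by full permutation enumeration; above that a t approximation with
n − 2 degrees of freedom is used (the reference analysis does not state its
p method). `correlation_table()` assembles the 5 × 4 score-by-feature
matrix with listwise deletion per pair and flags p < 0.05 per cell without
multiple-testing correction, matching the per-cell starring convention of
exploratory digital-biomarker tables; Benjamini–Hochberg adjustment is one
argument away.

## Numerical choices

* Moving SD runs streaming over prefix sums after centring each covered
  span; centring keeps the accumulators small, and the result matches
  direct per-window recomputation to ~1e−13 g (tested against a brute-force
  oracle on 1,000 random series).
* Schedules round bout boundaries to whole seconds so durations sum exactly.
* Threshold comparisons are strict (`> 0.01 g`), the gap rule is strict
  (`< 1 s`), and a single eligible window counts as an event.
* All randomness flows from explicit seeds through derived per-stage
  sub-seeds; rerunning any stage with the same config and seed is
  byte-identical.

## Problem sizes used in the shipped checks

The test-suite and acceptance checks run at desk scale, chosen to finish in
minutes on one CPU while leaving comfortable statistical margins: detector
fidelity on a 10-h stationary recording with ~100 planted bursts; classifier
evaluation on an 18-subject bank (10 scripted minutes each) under the
14/2/2 split; correlation recovery on 100 cohorts of n = 33 and 200 cohorts
of n = 200 at day-level resolution; and a 4-patient signal-level pipeline
run for the determinism check.

## Limitations

* The generator's gait and gesture models are caricatures: no real device
  noise, posture drift, or non-wear misclassification. Detector fidelity on
  synthetic bursts bounds what the rules do under their own assumptions,
  not clinical performance.
* Hand work is modelled (and detected) as sustained supra-threshold
  stationary movement, so it floods the gesture channel when present — the
  known limitation that instrumental hand activity is not separated from
  communicative gesturing.
* Gestures during ambulatory time are out of scope by definition of the
  detector.
* The shipped classifier is the feature baseline; the conv-recurrent
  variant is interface-reserved only.
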