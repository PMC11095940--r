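---
title: "Methods: valence preference analysis of single dopamine axons"
author: "AxonValence package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: valence preference analysis of single dopamine axons}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AxonValence)
```

# Scope and model of the data

AxonValence analyses two-photon calcium imaging of individual
mesocortical dopamine axons recorded while a head-fixed mouse receives
water rewards and mild tail shocks, first with unpredictable timing and
then in a trace-conditioning task in which a 2 s pure tone predicts the
outcome after a 1 s stimulus-free delay. The unit of analysis is the
*session bundle*: an ROI-by-frame raw fluorescence matrix (the output of
upstream motion correction and segmentation), per-frame registration
shifts, an event timeline (trial conditions, CS/US onsets), and
behavior traces (a tongue-position keypoint series and treadmill
speed), all sharing one clock with t = 0 at session start. Windows are
half-open `[start, end)` and frame `i` covers `[i/fs, (i+1)/fs)`;
window boundaries snap to the nearest frame at or before the boundary,
never interpolating.

The scientific questions the pipeline answers are: (i) does an axon
respond to reward, to aversive stimuli, or to both, and with which
preference (the polar angle of its response vector); (ii) how do cue
and outcome responses evolve over days of conditioning within clusters
fixed before learning; and (iii) on a trial-by-trial basis, is cue
discrimination (read out from anticipatory licking or facial-expression
embeddings) accompanied by sharper cue selectivity.

# Preprocessing

**dF/F.** The baseline F0 is the 50th percentile of the raw trace in a
30 s sliding window, centered on the current frame and truncated at the
session edges, and dF/F = (F − F0)/F0. The window is centered rather
than causal because its purpose is symmetric drift removal, not online
estimation; percentiles use the standard type-7 definition, and the
implementation (a small C++ kernel) is checked element-wise against a
brute-force per-frame percentile oracle at 1e-12. If F0 is nonpositive
at some frame it is floored at the ROI's 1st percentile of raw
fluorescence; if that floor is itself nonpositive the ROI cannot be
normalised and an error names it.

**ROI deduplication.** Segmentation splits one axon into several ROI
fragments with near-identical traces. Pairs of dF/F traces with
full-session Pearson correlation above 0.65 are linked, linked ROIs are
grouped into connected components (the linkage rule is deliberately the
weakest one consistent with "grouped into clusters"), and each
component keeps one representative; the procedure iterates on survivors
until all remaining pairs are at or below threshold, which is asserted
as a post-condition in the tests. "Largest signal" is implemented as
the largest temporal standard deviation of dF/F — a robust proxy for
response strength; the maximum value is a noisier alternative and is
noted here for users who want it. Ties are broken by a seeded draw so
results are reproducible and input-order invariant. Zero-variance
traces have undefined correlations and are excluded with a warning.

**Brain movement.** Frame-to-frame registration increments in x and y
are combined trigonometrically into a displacement magnitude in
microns (16 pixels = 5 um). The report carries the RMS of that trace
(computed on sequential shifts, not absolute positions) and movement
events: upward crossings of 5 um by the displacement trace after a
2nd-order zero-phase Butterworth low-pass at 1.5 Hz (order and phase
behaviour are package choices; zero-phase filtering avoids onset-time
bias), debounced by one sub-threshold frame.

# Event-triggered responses

Per-trial response amplitude is the mean dF/F in the signal window
minus the mean in the control window. For unconditioned events both
windows anchor to the event: control `[-2, 0)` s, signal `[0, 2)` s.
For conditioned trials the control window anchors to the CS onset for
*both* cue and outcome responses, so that outcome amplitudes are
measured against the pre-cue baseline; reward-omission trials use a
`[0, 4)` s signal window at the expected reward time. Significance per
axon and event kind is a one-sided paired Wilcoxon signed-rank test of
per-trial signal means against control means ("activity larger than
baseline"); a two-sided option exists. The test pairs windows within a
trial rather than pooling distributions — the signed-rank test is a
paired test, and pairing absorbs slow trial-to-trial state changes. We
require at least 6 paired trials, the smallest n at which one-sided
p < 0.05 is attainable; below that the axon is flagged undetermined
rather than non-significant. No correction across axons is applied by
default, matching the per-axon p < 0.05 rule; Benjamini-Hochberg is
available as an option. An axon is *responsive* if either the reward or
the aversive response is significant; only responsive axons enter
preference clustering. Locomotion responses reuse the same machinery on
spontaneous bout initiations, excluding initiations within 2 s of any
US.

# Valence preference

The preference statistic is the polar angle of the (reward, aversive)
amplitude pair: 0 deg purely reward-preferring, 90 deg purely
aversive-preferring. The full-plane two-argument arctangent is used, so
negative amplitudes are retained rather than clipped — near-origin
scatter is real data, and clipping would bias angles toward the axes.
The population density of angles uses a Gaussian kernel wrapped on the
circle; a wrapped rather than truncated-linear kernel was chosen
because angles are circular even though most mass lies in the first
quadrant. The automatic bandwidth is a circular Silverman rule (normal
reference bandwidth on the circular standard deviation).

Clusters are fit by k-means (k = 2, 50 restarts, seeded) on the raw
response pairs; both axes share dF/F units, so no standardisation is
applied, matching how the scatter is drawn. The cluster with the
smaller circular-mean angle is labeled reward-preferring. The reported
decision-boundary angle is where the perpendicular bisector of the two
centroids crosses the circle of median response magnitude — the angle
at which a typical-magnitude response flips assignment. The exact
k-means initialisation of any particular historical analysis is
unknowable, so the tests assert recovery and stability on separated
data rather than bit-level agreement.

Circular comparisons (e.g. first day vs late phase of per-axon angles)
use a seeded permutation test: in the paired mode the wrapped per-axon
differences are sign-flipped and the statistic is the magnitude of the
mean sine component — under the symmetric null the sine components are
sign-symmetric, and this component retains power for shifts near 90
deg, where the magnitude of the circular-mean angle itself does not.
No named classical circular test is assumed because none is uniformly
valid for paired angle data of this kind; users should note the test
is assumption-free but permutation-based. Shifts near 180 deg are
directionally ambiguous and outside the regime of interest.

The learning-phase course fixes cluster labels from the
pre-conditioning session and never re-fits them per phase; per-phase
amplitudes pool each axon's trials across the phase's days and re-run
the signed-rank machinery on the pooled trials. Axons missing from a
phase are reported absent, never imputed.

# Behavior

Licks are upward crossings of the tongue keypoint past half the spout
position, debounced at 50 ms; the event rule is an artifact definition
(the upstream study tracked keypoints but did not state an event rule)
and is configurable, and a hardware lick-sensor event stream can be
substituted. Locomotion bouts are maximal runs above the session
median + 0.5 SD lasting over 200 ms; initiations require 0.5 s of
sub-threshold quiescence. The SD is the population SD of the full
session, exactly as the threshold formula is usually written; because
the rule is affine-equivariant the detector is invariant to rescaling
of the speed trace, and units are irrelevant. Anticipatory behavior is
any event (or bout overlap) in `[CS onset, US onset)` — the full cue
plus delay window, matching the trial-classification definition, not
the delay alone. Learning phases: day 1 stands alone; remaining days
split into three (or six) contiguous, as-equal-as-possible blocks,
earlier blocks taking the extra day.

# Cue discrimination

Conditioned trials are classified into four groups by condition and
anticipatory licking (correct reward = lick after the reward cue,
correct aversive = no lick after the aversive cue, and the two error
groups). The facial-expression decoder consumes precomputed per-frame
embedding features (the video-to-embedding network is out of scope).
The pipeline is: one-way ANOVA F-value ranking with the top 400
features kept, re-fit *inside every training fold* (feature selection
on the full day would leak test labels; the tests audit this);
a class-balanced ensemble in which each of 25 members is a random
forest trained on all minority-class trials plus an equal-sized
majority subsample drawn without replacement (the member count is not
dictated by any source; 25 is large enough for stable votes and odd to
avoid ties, and is configurable); majority vote across members;
stratified fivefold cross-validation within each day; and balanced
accuracy — per-class accuracies averaged with equal weight, which is
exactly 50 percent in expectation for label-independent features at
any imbalance. Time courses re-run the entire pipeline on within-window
feature means (500 ms windows stepped by 160 ms); within-window means
rather than concatenated frames keep the feature dimension constant
across windows.

The correct-vs-incorrect contrast compares, per axon, mean cue
amplitudes between correct and incorrect trials of each condition
(paired Wilcoxon across axons) and compares correctness-stratum polar
angles with the circular permutation test. If a session has no
incorrect trials the contrast is undefined and the error message
points at analysing an earlier phase with errors (mirroring the
standard fallback to the middle phase).

# The synthetic-session generator

Real sessions of this kind are not publicly deposited, so the package
ships a generator whose defaults *are* the study conditions: a 7:1:1
reward:aversive:control trial mix, ITIs uniform on 55-65 s, a 2 s tone
plus 1 s trace delay (US 3 s after CS onset), first-lick latency
0.538 +/- 0.065 s after reward, shock-evoked running with probability
0.9, anticipatory licking and running following a logistic learning
curve from a 0.05 floor to 0.85 (licking) / 0.7 (running) with midpoint
day 6 of 12, and a von Mises angle mixture with modes at 15 and 75 deg
and weights 0.25/0.75. The mixture concentration (kappa = 20 per
component, circular SD about 13 deg) is the generator's design point:
it is the broadest concentration at which a 25/75 mixture 60 deg apart
still produces the bimodal angle density the analysis is meant to
exhibit; no generative model is dictated by the source data.

Fluorescence is `B0 (1 + drift + signal + noise)`: a per-ROI baseline
drawn from 80-120 a.u., a slow sinusoidal drift (5 percent amplitude,
300 s period, random phase), and a signal that sums instantaneous-rise
exponential-decay transients (tau = 0.5 s; a single-exponential kernel
is sufficient for window statistics, which never resolve rise
kinetics). Each axon responds to reward with amplitude A cos(theta)
and to shock with A sin(theta) (A in 0.5-1.5 peak dF/F), to cues with
a day-1 amplitude of 0.4 A for both tones, and fires spontaneous
transients at 0.1 Hz. Across learning, aversive-preferring axons ramp
their aversive-cue amplitude threefold (with a mild reward-cue
attenuation) while US responses habituate to 0.6 of day 1 — so the
phase-course trends exist in the ground truth and recovery can be
tested end to end. Duplicate ROIs (30 percent of axons have 2-3)
share the axon's event train with a gain in 0.7-1.3 and independent
Gaussian noise (SD 3 percent of baseline). At these settings duplicate
pairs exceed the 0.65 dedup correlation in over 95 percent of cases —
a contract the generator must satisfy for the deduplication premise
("fragments of one axon are near-perfectly correlated") to be
emulated; the noise and spontaneous-rate defaults were fixed together
to honour that contract and reflect the large transients of modern
GCaMP indicators in sparse axons.

Behavior traces are generated at 65 Hz (tongue) and 100 Hz (speed).
The hardware-native speed sampling of such rigs is far higher, but the
locomotion detector uses only rank statistics of the trace, so the
rate is a desk-scale choice, not a modelling claim. Facial features
are i.i.d. standard normal per trial, frame and feature, with a
configurable subset (default 20 of 500) shifted by a configurable
effect size during the cue window on aversive trials; effect size 0
yields chance decoding by construction.

What the generator does **not** emulate: motivational-state coupling
(animals stopping licking under strong shocks), imaging noise
correlated across ROIs (neuropil), GCaMP nonlinearity and saturation,
slow representational drift across days, and any anatomical structure.
Passing tests therefore demonstrate that the *analysis* recovers what
it assumes from data of the assumed structure — not that real recordings
satisfy those assumptions.

# Numerical and scale choices

All randomness flows from one seed through deterministic per-stage
child seeds; identical config + seed reproduces every output byte for
byte. The session container is a plain-text CSV + JSON directory with
doubles serialised at 17 significant digits (bit-exact round trip).
Problem sizes used by the shipped tests and the acceptance script are
chosen for a single CPU: 18-trial sessions, populations of 8-200
axons, 12-day experiments with 20 axons, 100-session dedup sweeps,
2,000-replicate calibrations, and 20 replicates of the 200-trial
decoder chance calibration. These sizes are the package's validation
design; all are configurable upward.

Known limitations: the dedup representative choice can differ between
runs only for exactly tied SDs (resolved by the seeded tie-break); the
sliding-percentile baseline biases dF/F near session edges (windows
truncate), so the generator leads sessions in and out by ~20-35 s and
edge trials are dropped from tensors; the paired circular test has no
power against exact 180 deg reversals; and k-means preference clusters
are only meaningful when the population is genuinely bimodal — the
boundary-angle diagnostic makes that visible.
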