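---
title: "Myoelectric intention estimation and compensatory-movement analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Myoelectric intention estimation and compensatory-movement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myocomp)
```

`myocomp` studies a single question computationally: when a myoelectric
prosthesis controller can tell wrist motion apart from hand motion, and the
socket leaves the wrist free, how much compensatory trunk and elbow movement
disappears? This vignette documents the models behind each stage, the
parameters that matter, what the synthetic data do and do not emulate, and
the numerical choices a maintainer would want written down.

## 1. The feature chain

Raw surface EMG is modeled as already digitized at 2,000 Hz from three
forearm electrode sites. The chain is:

1. **High-pass, 50 Hz.** A 4th-order Butterworth applied forward–backward
   (`signal::filtfilt`), so the filter is zero-phase — appropriate for
   offline analysis, where lag correction matters more than causality. The
   filter order is a package choice; the cutoff removes motion artifact and
   most line interference.
2. **Framing.** Hann window (periodic form), frame size 256 samples
   (128 ms), hop 128 samples. The hop is a package choice: 50% overlap is
   the standard compromise for Hann analysis and is configurable.
3. **FFT and band powers.** Per frame, `|X_k|^2` over the non-negative bins,
   then the **mean** of `|X_k|^2` over the bins whose center frequency falls
   in each of eight equal 50-Hz bands on [0, 400) Hz. The mean (rather than
   the sum) makes bands with six vs seven bins comparable; bins at or above
   400 Hz are discarded; the DC bin belongs to band 0 and is ≈0 after the
   high-pass. Equal-width bands are an assumption — only the count (8) and
   the range (0–400 Hz) are fixed by the protocol being modeled.

Three channels × eight bands gives the 24-dimensional feature vector. With
log-compression off, features are non-negative and scale as the square of
input amplitude; the pipeline enables `log(1+x)` compression before
training, which tames the dynamic range without affecting any of the
band-power contracts.

## 2. Intention estimation

**Teacher data.** For each taught segment, frames whose centers lie in
`[start + 0.5 s, start + 2.0 s]` are buffered with the taught label. The
0.5-s skip avoids contraction-onset transients; both times are package
choices (configurable) since only the buffering principle is fixed.

**Classifier.** A single-hidden-layer feed-forward network (16 logistic
hidden units via `nnet`, softmax output, weight decay 1e-4, at most 500
BFGS iterations) on z-scored features. This is deliberately the smallest standard
network adequate for a 24-dimensional, five-class problem; all
hyperparameters are arguments. Training is deterministic given the seed
(which fixes the weight initialization); hitting the iteration cap logs a
warning but still returns the model, and in practice the benchmark scenario
reaches training accuracy 1.0 well before the cap matters.

**Recognition-stabilization filter.** The raw prediction stream chatters;
the filter looks at the last `window = 10` frames (0.64 s at the default
hop) and adopts the modal label only when its proportion reaches
`τ = 0.6`, otherwise holding the previous output (initially rest). Ties
break toward the earliest label in the canonical order, for determinism.
This is the simplest reading of "adjust the output by the proportion of
estimates within a period"; both parameters are configurable. Two
consequences are tested as properties: the output never switches more often
than the input, and isolated single-frame misclassifications are absorbed
entirely for any window ≥ 2 at τ = 0.6 (two switches in consecutive frames
would require more agreeing frames than the overlapping windows can hold).

**Hand-command mapping.** Wrist flexion and extension are trained as
explicit classes and mapped — together with rest — to `hold`; only grip and
open drive the hand. The alternative (rejecting wrist activity by a
confidence threshold) is deliberately not implemented: the explicit-class
reading is testable end to end, and the wrist-invariance property (wrist-only
activity produces zero open/close events through the whole loop) is the
computational core of the claim that a free wrist does not disturb the hand.

## 3. Kinematics

**Trunk angle.** Only the two shoulder landmarks are guaranteed, so the
trunk angle at frame k is defined as the signed angle of the left→right
shoulder segment against horizontal (degrees, positive when the right
shoulder is higher). This is an interpretation — a hip-referenced angle
would need landmarks the protocol does not track. It is translation
invariant and flips sign under mirroring (mirroring means negating x *and*
swapping the anatomical left/right labels).

**Distortion level.** `D(Θ) = Σ |θ_k|`, a plain frame sum. The printed
magnitudes this models (≈4.2-s trials at 0.11 s/frame with ≈10° tilt giving
distortions in the hundreds) match the plain sum, not a Δt-weighted
integral, so the Δt multiplier defaults to 1 and ×0.11 is an option. The
statistic is non-negative, additive under concatenation, and positively
homogeneous — all tested.

**Trajectories.** Trials are resampled to the longest trial's length by
linear interpolation uniform in sample index (the simplest reading of
"interpolate the missing data to unify trials"; arc-length parameterization
would change checkpoint placement and is not used). Endpoints are preserved
exactly and resampling is idempotent at a fixed length. The mean path is the
per-index mean; dispersion is reported as per-axis SDs at the six
checkpoints dividing the path into five equal parts. Base and end heights
are the task-side elbow y at the grasp and release frames, which the
simulator annotates; for real data the loader falls back to first/last
frame only if no annotation exists.

## 4. Evaluation

Trials longer than 10 s are excluded (a trial of exactly 10 s is retained —
the cutoff reads "more than 10 s"); trials over 4 s are flagged as slow for
annotation only. Distortion histograms use right-open bins of width 50
anchored at 0, with the sample mean/SD as the normal overlay. The t test
defaults to paired-by-trial-index when condition counts match (consistent
with 29 degrees of freedom arising from 30 trial pairs) and Welch otherwise;
the variant and n are always recorded, since the pairing assumption cannot
be verified from summary data. Degenerate inputs are resolved by contract:
identical paired samples give t = 0, p = 1; a constant nonzero difference is
a "zero variance" error surfaced as a reported non-result rather than a
crash. No multiple-testing correction is applied — the design reports single
comparisons. Throughput is reported as the mean number of completions per
consecutive 30-s window over a long continuous session assembled from
trial-plus-return cycle times, which is what a per-30-s block count
converges to.

## 5. What the generators emulate — and what they do not

**EMG.** Each class contributes band-limited Gaussian noise (2nd-order
Butterworth band-pass of white noise, normalized to unit RMS) scaled by
per-channel gains and multiplied by a smoothed on/off envelope with a
100-ms rise, on top of white sensor noise, a 50-Hz line component, and
optional channel crosstalk. Grip and open occupy 60–150 Hz with flexor- vs
extensor-dominant gains; the wrist classes share muscles but sit at
120–250 Hz. This reproduces the *statistical* structure the feature chain
assumes — stochastic, band-shaped, class-separable activity — and nothing
physiological: no motor-unit trains, no fatigue, no electrode lift, no
inter-subject variability. Passing control-loop tests therefore show the
pipeline is correct and the class geometry is learnable, not that a given
human would reach the same accuracy.

**Kinematics.** Trials draw a duration, a base and an end height, and a
tilt amplitude from normal distributions; the tilt profile is a half-sine
(the simplest smooth 0 → peak → 0 shape with a controllable peak), the elbow
descends along a smoothstep between annotated grasp and release frames, and
every coordinate gets 0.2-cm Gaussian measurement noise — a stylized stand-in
for pose-estimation jitter, chosen so that the rectification bias it adds to
D (noise inflates |θ| near θ = 0) stays near 2% of the separate-condition
mean. Frame timestamps are exact multiples of 0.11 s unless the optional
±1% jitter is enabled.

**Presets.** `"table1_C"` encodes the published right-arm participant
summaries: base/end heights 45.1/27.6 cm (conventional) and 22.2/10.0 cm
(separate) with their printed SDs; tilt amplitudes 7.90° and 3.90° obtained
by inverting the half-sine frame sum `D = A · cot(π/2n)` against the
published distortion means 192 and 90.2 at the expected frame counts, with
tilt SDs 2.46° and 2.15° derived the same way from the published distortion
SDs net of the duration-variance contribution; durations 4.2 ± 0.5 s and
4.0 ± 0.5 s; inter-trial return times 2.30 s and 1.36 s so that cycle times
reproduce the published 4.6 and 5.6 blocks per 30 s. `"table2_D"` encodes
the left-arm user analogously. Trial-level distributions are nowhere
published, so these presets are explicitly stylized: they pin means (and,
where invertible, SDs) and assume normality and independence everywhere
else. The per-trial tilt draw is truncated at zero, which biases the
separate-condition distortion mean upward by under 1% — accepted rather than
patched, and visible in the recovery tests, which compare the measured
distortion to the generator's own realized truth rather than to the nominal
target.

## 6. Numerical choices and degenerate inputs

* Band-power oracle agreement (FFT path vs direct DFT) is asserted to 1e-9
  relative error; the windowed Parseval identity likewise.
* Resampling uses `stats::approx` on each axis; identity at the source
  length is exact, so idempotence is asserted with `identical()`.
* Coincident shoulder landmarks, empty teacher data, single-class training
  sets, streams shorter than one frame, empty histograms, and schedules that
  overrun the recording are all hard errors with named messages.
* A zero-tilt scenario produces all-zero distortions; the comparison then
  reports t = 0, p = 1 (identical pairs) or a recorded "zero variance"
  non-result instead of aborting.
* Problem sizes used by the shipped analyses: 200 trials per condition for
  parameter recovery (SEs of ≈0.1 cm on a 22.9-cm contrast), a 60-s teaching
  session plus an independent 60-s estimation session for the control loop,
  and 1,000 replicates of 30 paired draws for the power check — sizes chosen
  so each analysis's Monte-Carlo error is far below the effects it measures.

## 7. Known limitations

* The classifier, buffer timings, and stabilization parameters for the real
  individuality-adaptive controller are not public; the defaults here are
  package choices, clearly surfaced as arguments.
* Trunk angle from shoulders alone conflates lateral lean with shoulder
  elevation asymmetry; with only four landmarks this is unavoidable.
* The simulators are 2-D (camera plane) and do not model pose-estimation
  failure modes such as landmark swaps, which the real video pipeline
  exhibits.
* Throughput modeling assumes independent trial cycles; real sessions show
  learning and fatigue trends the generator does not emulate.
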