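---
title: "Simulating a closed-loop hybrid EEG-fMRI neurofeedback platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a closed-loop hybrid EEG-fMRI neurofeedback platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridnf)
```

## What this package simulates

Hybrid neurofeedback platforms acquire EEG and fMRI simultaneously,
clean both signals in real time, reduce each to a scalar feature, and
present the combination back to the subject so they can learn to
self-regulate. Testing such a platform on hardware is slow and
irreproducible. `hybridnf` re-creates the entire loop on a desk:
ground-truthed synthetic acquisition, the real-time processing chains
of both modalities, the feedback engine, a deterministic two-layer
scheduler, and a simple self-regulating subject model that closes the
loop. Because every stage has known ground truth and a single seed, any
pipeline property — artifact suppression, estimator correctness, timing
invariants, even "does feedback help learning" — becomes a testable
assertion.

## The synthetic recording

`gen_eeg()` builds clean EEG as broadband Gaussian noise plus 8–30 Hz
rhythms on two "motor" channels. The rhythms are narrowband-filtered
noise, not fixed-phase sinusoids: a real mu or beta rhythm carries a
random, slowly drifting phase, and this matters here because a pure
sinusoid whose frequency times the repetition time (TR) is an integer
would be exactly TR-periodic and would be absorbed by the gradient
artifact template — a pathology no real recording exhibits. During Task
blocks the rhythm amplitude is scaled by `1 - erd_depth * s`, where `s`
in [0, 1] is the subject's regulation state: the event-related
desynchronization (ERD) that motor imagery produces.

On top of the clean signal:

* a **gradient artifact** — one fixed band-limited pseudo-random
  waveform repeated exactly once per TR, scaled so its RMS is
  `artifact_gain` (default 100) times the clean RMS. Scanner gradient
  artifacts are near-identical within each TR, which is precisely the
  property average-artifact subtraction exploits;
* a **ballistocardiogram (BCG)** — a damped-sinusoid pulse (~0.3 s,
  ~7 Hz) placed 0.15 s after each R peak on every EEG channel with
  per-channel amplitudes of a few times the clean RMS;
* an **ECG channel** with sharp biphasic R spikes, itself contaminated
  by the gradient (as in real recordings) but free of BCG.

The default heart rate is 66 bpm with 20 ms per-beat jitter. The
default is deliberately incommensurate with the 2 s TR: at exactly
60 bpm a jitter-free heart fires exactly twice per TR, the cardiac
artifact becomes TR-periodic, and the gradient template silently
swallows it together with the ECG spikes. No physical heart is
phase-locked to a scanner, so the simulator should not be either.

`gen_fmri()` gives every voxel a baseline (100), a global linear drift,
and Gaussian noise; voxels in a 3×3×1 active block additionally carry
`beta` times the canonical double-gamma haemodynamic response function
(HRF) convolved with the task design, modulated per volume by the
subject state. The kernel is normalized to unit sum so a long task
block plateaus at `beta`, making `beta / noise_sd_bold` the per-voxel
SNR (default 10). The top slice never activates and serves as the
background region for global-signal correction. The invariant
`contaminated = clean + gradient + bcg` holds to machine precision, and
identical configurations reproduce bitwise-identical outputs.

What the generator does **not** emulate: realistic electrode-space
mixing (no forward model), respiration and scanner-ventilation
artifacts, head motion, multi-subject variability, spatially
heterogeneous drift. Passing tests therefore demonstrate the
correctness and calibration of the *processing*, not performance on
real recordings.

## EEG pipeline

**Average-artifact subtraction (AAS).** `template_correct()` implements
the sliding-template method for both artifact types: epochs are
anchored on TTL markers (gradient; 5–15 epochs, default 10) or R peaks
(BCG; 10–20 epochs, default 15); each new epoch is corrected by
subtracting the mean of the buffered *raw* epochs and is then pushed
into the buffer. For any strictly epoch-periodic artifact this cancels
exactly from the second epoch on, and the operation is linear. The
warm-up policy is not dictated by the method itself; here epochs before
the buffer fills are corrected with the partial mean and flagged —
output is defined from the first anchor, and only epoch 0 passes
through raw. Epoch length is the minimum anchor spacing in gradient
mode (exact tiling, with a desynchronization error if spacing varies)
and the median spacing in BCG mode (robust to a single short outlier
under heartbeat jitter).

The price of AAS is template noise: the template contains 1/B of the
clean EEG of the buffered epochs, so the corrected signal is
`clean - mean(B past clean epochs)`, bounding the corrected-vs-clean
correlation near `1/sqrt(1 + 1/B)` (≈ 0.97 for B = 15) even when the
artifact itself is removed perfectly. When both corrections run in
series the floors compound — worth remembering when interpreting
correlation-based quality metrics.

**R-peak detection.** A Pan-Tompkins-style detector: 5–15 Hz band-pass,
derivative, squaring, 150 ms moving-window integration, threshold at
the larger of 4 MAD and a quarter of the 99.9th percentile of the
energy envelope (the percentile term ignores low-amplitude
template-subtraction ghosts), refractory suppression of 0.3 s, strongest
humps first. The fine anchor within each detected complex is the steep
zero crossing between its two dominant opposite lobes. That choice is
deliberate: the envelope maximum wobbles by a few samples, and the
largest-|y| lobe flips sides between re-detections on streamed
segments; either jitter smears the BCG template. The zero crossing is
sample-accurate and independent of polarity and of segmentation.

**Features.** Signals are band-passed to 8–30 Hz (zero-phase
order-4 Butterworth), segmented into 2 s windows with 95% overlap for
calibration, and projected through common spatial patterns (CSP)
filters trained on Task/Rest covariances (generalized eigenproblem on
trace-normalized covariances, 3 filter pairs, shrinkage applied only if
a covariance is rank-deficient, eigenvalue ties broken by index). The
per-window feature is the mean log-variance of the projected
components; doubling the amplitude moves it by exactly `log 4`.

## fMRI pipeline

Each arriving volume passes motion-correction and slice-timing *stubs*
(pass-through interface slots — rigid-body registration is a solved
problem handled by external tooling in hardware deployments and is out
of scope here), separable Gaussian smoothing (FWHM 4 mm, replicate
padding so constants are preserved), ROI mean extraction, and the
incremental general linear model (iGLM). The iGLM accumulates
`X'X`, `X'y`, `y'y`, and the scan count, so per-scan cost is O(p²)
regardless of history and the estimates at scan k equal a batch
least-squares fit on the same prefix — the module's central invariant,
tested to 1e-8. The online design matrix is intercept + linear drift +
HRF-convolved task regressor. t-maps convert to z through the normal
quantile of the t CDF (computed on the log scale so very large t do not
overflow). Calibration selects the feedback ROI as the
highest-peak 6-connected cluster above z = 3 with at least 4 voxels
(thresholds scaled to the small default grid); ties are broken by size
then lowest linear index, so selection is deterministic.

## Feedback engine

Both modalities use average percent signal change (APSC) against a rest
baseline. For ROI BOLD the ratio form `100 (x - b) / |b|` is computed
with the ROI's rest-level mean as the scale and the background-region
deviation subtracted first, so global drifts cancel. For the EEG
feature the ratio of two log-powers is meaningless, so a difference
form is used and — because these are ERD protocols, where *success
lowers* band power — the sign is flipped: feedback is positive when
power drops. Baselines are re-established at the end of every Rest
block (replacement policy; a cumulative option exists and is the
calibration default for the initial baseline, which averages all
calibration rest intervals). Feedback is normalized onto [0, 1] between
a floor of 0 and a per-modality target equal to the calibration-session
task modulation rescaled to full regulation, then combined (2-vector,
mean, or weighted; the subject model always sees the scalar mean).
Negative values display as 0 — the display metaphors are
maximize-toward-target.

## Scheduler and closed loop

The two-layer design: acquisition cursors anchored on the first TTL
pulse, feedback-update callbacks every `update_period` (0.5 s default),
and protocol callbacks that may only fire *on* update ticks — enforced
by requiring fixed block durations to be multiples of the update period
and by snapping flexible task blocks to the first tick after their
target is reached (target rule: normalized feedback at 1.0 on two
consecutive ticks). Everything runs on a simulated clock: all
randomness is drawn up-front from the run seed, the tick loop itself is
RNG-free, and identical arguments give byte-identical event logs, which
turns timing invariants (samples on the tick lattice, transitions ⊆
ticks, causality under the configured 200 ms EEG / 150 ms fMRI
processing latencies) into exact assertions. `check_sync()` compares
observed TTL times against the nominal TR lattice — an isolated
off-lattice pulse is an acquisition delay, a ~TR-sized gap a missed
TTL, three growing offsets clock drift — and `resync_or_abort()` makes
one re-anchoring attempt before stopping the session and flushing all
logs.

Three details of the online EEG path deserve record, because each
produced a measurable block-level bias before it was handled:

* pulse epochs overlapping the first (still-uncorrected) TR are never
  pushed into the BCG buffer — they would poison the template for the
  next 15 beats;
* the BCG buffer lags the acquisition head by one window length plus
  margin, so the template never contains samples of a window it later
  corrects; self-subtraction would deflate measured band power by about
  `1/capacity`;
* the session re-anchors the EEG baseline on the final seconds of the
  Begin period as processed by the *online* chain. The calibration
  baseline comes from the offline chain, whose residual artifact level
  is slightly different, and that offset would otherwise bias the whole
  first task block. Rest baselines likewise use only windows fully
  inside their block, so task-suppressed samples never leak in.

**Subject model.** First-order dynamics: during Task the state relaxes
toward 1 at rate `rate_task (1 + boost * gain * max(nfb, 0))`
(defaults 0.02 s⁻¹, boost 4); during Rest it decays at 0.025 s⁻¹; the
state is clamped to [0, 1] and idles during Begin. Sessions start at
the open-loop limit cycle (found by iterating the deterministic gain-0
map), so open-loop runs are block-stationary by construction and any
first-to-last-block trend is attributable to the feedback gain — the
learning surrogate the closed-loop test quantifies. This is the
simplest model exhibiting the phenomenon the platform exists to elicit;
it is not a model of human learning.

**Study conditions.** The closed-loop experiments use the standard
fixed design: 20 s Task / 20 s Rest repeated 10 times, update period
0.5 s, preceded by a 40 s Begin so the online templates (10 TRs
gradient, ~15 beats BCG plus causal lag) are fully established before
the first task block — with a shorter lead-in, template warm-up
masquerades as learning. Calibration runs the same block design
open-loop. The synthetic grid is 12×12×6 voxels so a complete
calibration-plus-session cycle takes a few seconds; all dimensions are
configurable upward.

## Numerical and degenerate-input choices

Zero-variance windows floor at `log(1e-12)` with a warning; a flat ECG
returns no peaks (warning, not error); an empty ROI mask is an error
because it signals failed calibration; singular iGLM designs name the
collinear columns, with an optional logged ridge fallback; `fwhm = 0`
smoothing is the identity; marker samples are 1-based inside R and on
disk (BrainVision convention), with conversions confined to the
readers/writers; all file writes are atomic (temp + rename) so an
aborted session never leaves truncated files; BrainVision data is
IEEE float32 multiplexed — one round trip quantizes doubles to single
precision, after which round trips are bitwise.

## Limitations

The generators are deliberately minimal; none of the artifact
corrections face sub-sample misalignment, electrode motion, or
non-stationary artifact shapes, so the measured suppression figures are
upper bounds on real-data performance. The AAS correlation floor means
"corrected equals clean" is unattainable by design, and correlation
targets must be read against that floor. The subject model's learning
is a surrogate used to validate loop plumbing, not a claim about
neurofeedback efficacy.
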