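# hybridnf

A fully synthetic, desk-scale re-creation of a **closed-loop hybrid
EEG–fMRI neurofeedback platform**, for researchers and engineers who
build or validate real-time neuroimaging pipelines and want every stage
— acquisition, artifact correction, feature extraction, feedback
computation, synchronization — testable against known ground truth,
without scanner time or deposited data.

## What it implements

* **Synthetic bimodal acquisition** with ground truth: multichannel EEG
  (narrowband 8–30 Hz motor rhythms with task-related
  desynchronization) contaminated by a TR-locked gradient artifact at
  100× the clean RMS and a heartbeat-locked ballistocardiogram (BCG),
  plus an ECG channel; BOLD volume series with a double-gamma
  haemodynamic response in an active block, global drift and noise.
* **Real-time EEG chain**: sliding-template average-artifact
  subtraction for both artifact types (`template_correct`), a
  Pan-Tompkins-style R-peak detector (`detect_r_peaks`), zero-phase
  band-pass (`bandpass`), overlapping-window segmentation
  (`segment_windows`), common spatial patterns training (`train_csp`)
  and log band-power features (`eeg_feature`).
* **Real-time fMRI chain**: Gaussian smoothing, ROI/background means,
  drift removal (`detrend`), an **incremental GLM** whose estimates at
  every scan equal batch least squares (`iglm`, `iglm_update`,
  `iglm_estimates`), and activation mapping with deterministic cluster
  selection (`activation_roi`).
* **Feedback engine**: percent signal change (`apsc`), z-scores, ROI
  size change, per-Rest-block baseline updates (`update_baseline`),
  unimodal/bimodal combination (`combine_nfb`) and display
  normalization.
* **Two-layer scheduler** on a simulated clock: update callbacks on a
  tick lattice, protocol transitions constrained to ticks, fixed and
  flexible block designs, typed desynchronization reports
  (`check_sync`) with resync-or-abort recovery, byte-identical logs per
  seed.
* **Closed loop**: a first-order self-regulating subject model converts
  feedback into deeper ERD and stronger BOLD responses
  (`subject_step`), so feedback efficacy itself is a testable property
  (`nfb_calibrate`, `run_session`).
* **I/O**: BrainVision (`.vhdr`/`.vmrk`/`.eeg`) and NIfTI-1
  readers/writers, YAML configs, tidy CSV/TSV logs, display-geometry
  mappings (`map_nfb`).

The feedback statistic is the average percent signal change of each
modality's feature against its rest baseline,
`APSC = 100 (x - b)/|b|` (difference form for log-power EEG features,
sign flipped so desynchronization counts as success), normalized to a
calibration-derived target and combined as `[EEG, fMRI]`, mean, or
weighted sum.

## Worked example

```r
library(hybridnf)

cfg <- sim_config(seed = 1)                    # 8-ch EEG @ 250 Hz, 12x12x6 grid, TR 2 s
pr  <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 10, begin_s = 40)

cal <- nfb_calibrate(cfg, pr)                  # CSP filters, ROI, baselines, targets
cal
#> <nfb_calibration>
#>   CSP: 6 filters, band [8, 30] Hz; ROI: 45 voxels
#>   EEG baseline 2.130 (target 0.321), fMRI baseline -0.003 (target 0.18%)

session <- run_session(cal, gain = 0.5, seed = 7)
summary(session)
#> Closed-loop session summary
#>   mean normalized NFB: task 0.566, rest 0.187
#>   task-block means: 0.534 0.552 0.551 0.554 0.580 0.519 0.588 0.618 0.596 0.568
#>   ROI GLM task t = 39.90; 0 sync report(s)
```

The calibration found a 45-voxel activation cluster and set each
modality's feedback target to its fully-regulated task modulation
(0.321 log-power units of ERD for EEG, 0.18% BOLD change for fMRI).
During the feedback run the normalized combined feedback averages 0.57
in Task blocks against 0.19 in Rest blocks — the subject modulates both
signals — the task regressor is recovered at t ≈ 40 by the incremental
GLM, the scheduler reports no desynchronization, and the task-block
means drift upward across the session: with `gain = 0` they stay level.
`plot(session)` shows the feedback trace against the subject state.

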