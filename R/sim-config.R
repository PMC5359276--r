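#' Simulation configuration
#'
#' Bundles every knob of the synthetic bimodal recording: EEG sampling,
#' scanner timing, grid geometry, artifact scaling and the task-modulation
#' model. Defaults emulate a standard simultaneous EEG-fMRI acquisition
#' (EEG digitized at 250 Hz, echo-planar imaging with a 2 s repetition
#' time) scaled down to a grid that simulates in seconds.
#'
#' @param seed integer seed; every random draw of the generators flows
#'   from it.
#' @param n_channels number of EEG channels (excluding the appended ECG
#'   channel). The first two channels act as "motor" channels carrying
#'   the task-modulated oscillations.
#' @param fs_eeg EEG sampling rate in Hz. `fs_eeg * tr` must be an
#'   integer so TR epochs contain a whole number of samples.
#' @param tr fMRI repetition time in seconds.
#' @param n_volumes number of volumes when a design is not supplied.
#' @param grid_shape integer vector of voxels per axis. The top slice
#'   (largest z index) never carries task activation and serves as the
#'   global background region.
#' @param artifact_gain ratio of gradient-artifact RMS to clean-EEG RMS
#'   (scanner gradient artifacts typically exceed EEG by two orders of
#'   magnitude).
#' @param heart_rate heart rate in beats per minute. The default is
#'   deliberately incommensurate with the default TR: a heart exactly
#'   phase-locked to the scanner is physically implausible and makes
#'   the cardiac artifact TR-periodic.
#' @param heart_jitter_sd standard deviation (seconds) of per-beat
#'   latency jitter.
#' @param erd_depth fractional band-power reduction on motor channels
#'   during task at full regulation, in \[0, 1\] (event-related
#'   desynchronization depth).
#' @param drift_slope scanner drift in signal units per volume, applied
#'   globally to every voxel.
#' @param noise_sd_eeg broadband EEG noise standard deviation (microvolt).
#' @param noise_sd_bold BOLD noise standard deviation (signal units).
#' @param beta task-activation amplitude of active voxels (signal units;
#'   `beta / noise_sd_bold` is the per-voxel SNR).
#' @param baseline_bold BOLD baseline level.
#' @param osc_freqs,osc_amp frequencies (Hz) and amplitude (microvolt) of
#'   the motor-channel oscillators inside the 8--30 Hz band.
#' @param bcg_amp peak amplitude of the ballistocardiogram pulse as a
#'   multiple of the nominal clean-EEG RMS.
#' @param active_block list with integer vectors `x`, `y`, `z`: the
#'   voxel block carrying task activation.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_channels = 8L,
                       fs_eeg = 250,
                       tr = 2.0,
                       n_volumes = 80L,
                       grid_shape = c(12L, 12L, 6L),
                       artifact_gain = 100,
                       heart_rate = 66,
                       heart_jitter_sd = 0.02,
                       erd_depth = 0.6,
                       drift_slope = 0.01,
                       noise_sd_eeg = 1,
                       noise_sd_bold = 0.1,
                       beta = 1,
                       baseline_bold = 100,
                       osc_freqs = c(10, 22),
                       osc_amp = 3,
                       bcg_amp = 4,
                       active_block = list(x = 5:7, y = 5:7, z = 3L)) {
  cfg <- list(seed = as.integer(seed), n_channels = as.integer(n_channels),
              fs_eeg = fs_eeg, tr = tr, n_volumes = as.integer(n_volumes),
              grid_shape = as.integer(grid_shape),
              artifact_gain = artifact_gain, heart_rate = heart_rate,
              heart_jitter_sd = heart_jitter_sd, erd_depth = erd_depth,
              drift_slope = drift_slope, noise_sd_eeg = noise_sd_eeg,
              noise_sd_bold = noise_sd_bold, beta = beta,
              baseline_bold = baseline_bold, osc_freqs = osc_freqs,
              osc_amp = osc_amp, bcg_amp = bcg_amp,
              active_block = active_block)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  spr <- cfg$fs_eeg * cfg$tr
  if (abs(spr - round(spr)) > 1e-9)
    stop("fs_eeg * tr must be an integer number of samples per TR (got ",
         spr, ")", call. = FALSE)
  if (cfg$artifact_gain < 0) stop("artifact_gain must be >= 0", call. = FALSE)
  if (cfg$erd_depth < 0 || cfg$erd_depth > 1)
    stop("erd_depth must lie in [0, 1]", call. = FALSE)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 1L))
    stop("grid_shape must be three strictly positive voxel counts",
         call. = FALSE)
  if (cfg$n_channels < 1L) stop("need at least one EEG channel", call. = FALSE)
  ab <- cfg$active_block
  if (any(ab$x < 1L) || any(ab$x > cfg$grid_shape[1]) ||
      any(ab$y < 1L) || any(ab$y > cfg$grid_shape[2]) ||
      any(ab$z < 1L) || any(ab$z > cfg$grid_shape[3]))
    stop("active_block must lie within grid_shape", call. = FALSE)
  if (any(ab$z == cfg$grid_shape[3]))
    stop("active_block may not touch the top (background) slice",
         call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  EEG: %d ch @ %g Hz  |  fMRI: %s grid, TR %g s, %d volumes\n",
              x$n_channels, x$fs_eeg,
              paste(x$grid_shape, collapse = "x"), x$tr, x$n_volumes))
  cat(sprintf("  gradient gain %g x clean RMS, heart %g bpm (jitter %g s)\n",
              x$artifact_gain, x$heart_rate, x$heart_jitter_sd))
  cat(sprintf("  ERD depth %g, beta %g, BOLD noise %g, drift %g/volume, seed %d\n",
              x$erd_depth, x$beta, x$noise_sd_bold, x$drift_slope, x$seed))
  invisible(x)
}

# number of EEG samples per TR epoch
samples_per_tr <- function(cfg) as.integer(round(cfg$fs_eeg * cfg$tr))

# nominal (analytic) clean-EEG RMS across channels, used where the realized
# signal is not yet available (online template scaling, ECG spike height)
nominal_clean_rms <- function(cfg) {
  v <- rep(cfg$noise_sd_eeg^2, cfg$n_channels)
  n_motor <- min(2L, cfg$n_channels)
  v[seq_len(n_motor)] <- v[seq_len(n_motor)] +
    length(cfg$osc_freqs) * cfg$osc_amp^2 / 2
  sqrt(mean(v))
}
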