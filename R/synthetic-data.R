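#' Task design boxcar from a protocol
#'
#' Samples the block design at volume resolution: one entry per acquired
#' volume, 1 during Task and 0 during Rest/Begin, plus an event list of
#' block onsets in seconds from session start.
#'
#' @param protocol a [protocol_spec()].
#' @param tr repetition time in seconds.
#' @return list with `boxcar` (numeric vector, one entry per volume) and
#'   `events` (data frame `kind`, `onset_s`, `duration_s`).
#' @export
gen_task_design <- function(protocol, tr) {
  blocks <- protocol$blocks
  if (protocol$mode == "fixed") {
    bad <- abs(blocks$duration / tr - round(blocks$duration / tr)) > 1e-9
    if (any(bad))
      stop(sprintf(
        "fixed-protocol block duration %g s is not a multiple of TR = %g s",
        blocks$duration[which(bad)[1]], tr), call. = FALSE)
  }
  dur <- ifelse(is.na(blocks$duration), blocks$max, blocks$duration)
  keep <- dur > 0
  blocks <- blocks[keep, , drop = FALSE]
  dur <- dur[keep]
  if (!nrow(blocks))
    return(list(boxcar = numeric(),
                events = data.frame(kind = character(),
                                    onset_s = numeric(),
                                    duration_s = numeric())))
  onsets <- cumsum(c(0, head(dur, -1)))
  nvol_block <- as.integer(round(dur / tr))
  boxcar <- rep(as.numeric(blocks$kind == "TASK"), times = nvol_block)
  events <- data.frame(kind = blocks$kind, onset_s = onsets,
                       duration_s = dur)
  list(boxcar = boxcar, events = events)
}

#' Canonical double-gamma hemodynamic response function
#'
#' The community-standard two-gamma kernel (response peaking near 5-6 s,
#' undershoot near 16 s, undershoot ratio 1/6), sampled at `dt` seconds
#' and normalized to unit sum so that convolution with a long task block
#' plateaus at 1.
#'
#' @param dt sampling interval in seconds (typically the TR).
#' @param duration kernel support in seconds.
#' @return numeric kernel vector.
#' @export
hrf_double_gamma <- function(dt, duration = 32) {
  t <- seq(0, duration, by = dt)
  h <- dgamma(t, shape = 6, rate = 1) - dgamma(t, shape = 16, rate = 1) / 6
  h / sum(h)
}

# discrete causal convolution of a regressor with a kernel, truncated to
# the regressor length
convolve_design <- function(x, kernel) {
  n <- length(x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    j <- seq_len(min(k, length(kernel)))
    out[k] <- sum(kernel[j] * x[k - j + 1])
  }
  out
}

# narrowband Gaussian oscillation around f Hz with unit RMS: real
# rhythms carry a random, slowly drifting phase, so they must not be
# phase-locked to the TR (a pure sinusoid with f * TR integer would be
# TR-periodic and partially swallowed by the gradient template)
narrowband_osc <- function(n, fs, f, halfwidth = 1.5) {
  bf <- signal::butter(2, c(f - halfwidth, f + halfwidth) / (fs / 2),
                       type = "pass")
  pad <- as.integer(2 * fs)
  y <- signal::filtfilt(bf, rnorm(n + 2L * pad))
  y <- y[(pad + 1L):(pad + n)]
  y / sd(y)
}

# damped-sinusoid ballistocardiogram pulse, ~0.3 s long, peak amplitude 1
bcg_pulse <- function(fs, length_s = 0.3, f = 7, tau = 0.08) {
  t <- seq(0, length_s, by = 1 / fs)
  p <- exp(-t / tau) * sin(2 * pi * f * t)
  p / max(abs(p))
}

# narrow biphasic spike emulating the QRS complex, peak amplitude 1
ecg_spike <- function(fs, width_s = 0.02) {
  t <- seq(-3 * width_s, 3 * width_s, by = 1 / fs)
  s <- -t / width_s * exp(-t^2 / (2 * width_s^2))
  s / max(abs(s))
}

# R-peak times (seconds) covering [0, total_s]: base interval 60/bpm with
# Gaussian per-beat jitter, enforcing a refractory gap
gen_r_peak_times <- function(total_s, heart_rate, jitter_sd,
                             refractory = 0.35) {
  base <- 60 / heart_rate
  times <- numeric(0)
  t <- 0.5
  while (t < total_s) {
    times <- c(times, t)
    gap <- base + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0
    t <- t + max(gap, refractory + 1 / 1000)
  }
  times
}

# fixed band-limited pseudo-random gradient template, one column per
# channel; unit RMS overall
gradient_template <- function(n_channels, len, fs) {
  bf <- signal::butter(4, 0.8, type = "low")
  tpl <- matrix(0, n_channels, len)
  for (ch in seq_len(n_channels)) {
    x <- rnorm(len + 200)
    y <- signal::filtfilt(bf, x)
    tpl[ch, ] <- y[101:(100 + len)]
  }
  tpl / sqrt(mean(tpl^2))
}

#' Generate a contaminated multichannel EEG recording with ground truth
#'
#' Clean EEG is broadband Gaussian noise plus 8-30 Hz oscillators on the
#' first two ("motor") channels, whose amplitude during Task blocks is
#' scaled by `1 - erd_depth * subject_state` (event-related
#' desynchronization under self-regulation). On top of it: a gradient
#' artifact that repeats a fixed waveform exactly once per TR, scaled so
#' its RMS is `artifact_gain` times the clean-signal RMS, and a
#' heartbeat-locked ballistocardiogram pulse at every R peak. An ECG
#' channel with visible R spikes is appended (it receives the gradient
#' artifact but no BCG). TTL markers are placed at every TR boundary.
#'
#' @param config a [sim_config()].
#' @param subject_trace regulation state in \[0, 1\], one value per
#'   volume (recycled); `NULL` means fully regulated (state 1).
#' @param design per-volume boxcar from [gen_task_design()]; `NULL`
#'   means all-rest.
#' @return list with `stream` (an [eeg_stream()], ECG as last channel)
#'   and `truth` (clean/gradient/bcg components, R-peak samples, the
#'   per-volume modulation actually applied).
#' @export
gen_eeg <- function(config, subject_trace = NULL, design = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  fs <- config$fs_eeg
  spt <- samples_per_tr(config)
  if (is.null(design)) design <- rep(0, config$n_volumes)
  nvol <- length(design)
  if (is.null(subject_trace)) subject_trace <- 1
  trace <- rep_len(subject_trace, nvol)
  nsamp <- nvol * spt
  nch <- config$n_channels

  # clean EEG: noise + task-modulated oscillators on motor channels
  clean <- matrix(rnorm(nch * nsamp, 0, config$noise_sd_eeg), nch, nsamp)
  mod_vol <- 1 - config$erd_depth * trace * design     # per-volume amplitude
  mod <- rep(mod_vol, each = spt)
  n_motor <- min(2L, nch)
  for (ch in seq_len(n_motor)) {
    for (f in config$osc_freqs) {
      osc <- narrowband_osc(nsamp, fs, f) * config$osc_amp / sqrt(2)
      clean[ch, ] <- clean[ch, ] + mod * osc
    }
  }

  # ECG channel: low noise + spike train (no task modulation)
  rms0 <- nominal_clean_rms(config)
  r_times <- gen_r_peak_times(nsamp / fs, config$heart_rate,
                              config$heart_jitter_sd)
  r_samples <- pmin(pmax(as.integer(round(r_times * fs)) + 1L, 1L), nsamp)
  ecg <- rnorm(nsamp, 0, 0.05 * rms0)
  spike <- ecg_spike(fs) * 10 * rms0
  half <- (length(spike) - 1L) %/% 2L
  for (r in r_samples) {
    idx <- (r - half):(r - half + length(spike) - 1L)
    ok <- idx >= 1L & idx <= nsamp
    ecg[idx[ok]] <- ecg[idx[ok]] + spike[ok]
  }
  clean_all <- rbind(clean, ecg)

  # gradient artifact: fixed template tiled once per TR, on all channels
  ngrad <- nch + 1L
  grad <- matrix(0, ngrad, nsamp)
  if (config$artifact_gain > 0) {
    tpl <- gradient_template(ngrad, spt, fs)
    grad <- tpl[, rep(seq_len(spt), nvol), drop = FALSE]
    target_rms <- config$artifact_gain * sqrt(mean(clean_all^2))
    grad <- grad * (target_rms / sqrt(mean(grad^2)))
  }

  # BCG: fixed damped-sinusoid pulse after each R peak, EEG channels only
  bcg <- matrix(0, ngrad, nsamp)
  pulse <- bcg_pulse(fs)
  lp <- length(pulse)
  bcg_delay <- as.integer(round(0.15 * fs))
  weights <- runif(nch, 0.5, 1) * config$bcg_amp * rms0
  for (r in r_samples) {
    i0 <- r + bcg_delay
    idx <- i0:(i0 + lp - 1L)
    ok <- idx >= 1L & idx <= nsamp
    if (!any(ok)) next
    bcg[seq_len(nch), idx[ok]] <- bcg[seq_len(nch), idx[ok]] +
      outer(weights, pulse[ok])
  }

  data <- clean_all + grad + bcg
  ttl_samples <- (seq_len(nvol) - 1L) * spt + 1L
  markers <- data.frame(kind = "TTL", sample = ttl_samples,
                        label = sprintf("V%d", seq_len(nvol)))
  labels <- c(paste0("EEG", seq_len(nch)), "ECG")
  labels[seq_len(n_motor)] <- c("C3", "C4")[seq_len(n_motor)]
  stream <- eeg_stream(data, fs, labels, markers)
  truth <- list(clean_eeg = clean_all, gradient_component = grad,
                bcg_component = bcg, r_peak_samples = r_samples,
                modulation = mod_vol, design = design)
  list(stream = stream, truth = truth)
}

#' Generate a BOLD volume series with ground truth
#'
#' Every voxel time course is baseline + global linear drift + Gaussian
#' noise; voxels inside the configured active block additionally carry
#' `beta` times the hemodynamic response convolved with the task design,
#' modulated per volume by the subject's regulation state. The top slice
#' never carries activation and serves as the background region for
#' global-signal correction.
#'
#' @inheritParams gen_eeg
#' @return list with `series` (a [volume_series()]) and `truth`
#'   (`true_betas` array, `active_mask` linear indices, the convolved
#'   regressor, baseline).
#' @export
gen_fmri <- function(config, design = NULL, subject_trace = NULL) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  if (is.null(design)) design <- rep(0, config$n_volumes)
  nvol <- length(design)
  if (is.null(subject_trace)) subject_trace <- 1
  trace <- rep_len(subject_trace, nvol)
  gs <- config$grid_shape

  kernel <- hrf_double_gamma(config$tr)
  reg <- convolve_design(design * trace, kernel)

  true_betas <- array(0, gs)
  ab <- config$active_block
  true_betas[ab$x, ab$y, ab$z] <- config$beta
  active_mask <- which(true_betas != 0)

  nvox <- prod(gs)
  noise <- if (config$noise_sd_bold > 0)
    matrix(rnorm(nvox * nvol, 0, config$noise_sd_bold), nvox, nvol)
  else matrix(0, nvox, nvol)
  drift <- config$drift_slope * (seq_len(nvol) - 1)
  flat_betas <- as.vector(true_betas)
  mat <- config$baseline_bold + noise +
    outer(rep(1, nvox), drift) + outer(flat_betas, reg)
  data <- array(mat, c(gs, nvol))
  series <- volume_series(data, config$tr)
  truth <- list(true_betas = true_betas, active_mask = active_mask,
                regressor = reg, baseline = config$baseline_bold,
                design = design)
  list(series = series, truth = truth)
}

#' One update-tick step of the self-regulating subject model
#'
#' First-order dynamics standing in for the human regulator in the
#' closed loop: during Task the state relaxes toward 1 at a base rate
#' that positive feedback accelerates (`rate * (1 + boost * gain *
#' max(nfb, 0))`); during Rest it decays toward 0. The state multiplies
#' the generators' task modulation, so stronger regulation means deeper
#' ERD and larger BOLD responses.
#'
#' @param state current regulation state in \[0, 1\].
#' @param task_on logical, inside a Task block?
#' @param nfb latest normalized feedback value (any sign; only the
#'   positive part acts).
#' @param gain feedback learning gain; 0 gives fixed open-loop dynamics.
#' @param dt tick duration in seconds.
#' @param rate_task,rate_rest base approach/decay rates (1/s).
#' @param boost dimensionless scaling of the feedback acceleration.
#' @return the new state, clamped to \[0, 1\].
#' @export
subject_step <- function(state, task_on, nfb = 0, gain = 0, dt = 0.5,
                         rate_task = 0.02, rate_rest = 0.025, boost = 4) {
  stopifnot(state >= 0, state <= 1)
  if (isTRUE(task_on)) {
    rate <- rate_task * (1 + boost * gain * max(nfb, 0, na.rm = TRUE))
    state <- state + dt * rate * (1 - state)
  } else {
    state <- state - dt * rate_rest * state
  }
  min(max(state, 0), 1)
}

# open-loop (gain 0) subject trace, one value per update tick of the
# protocol, starting from `s0`
open_loop_trace <- function(protocol, s0 = 0) {
  sched <- tick_schedule(protocol)
  s <- numeric(length(sched$task_on))
  cur <- s0
  for (k in seq_along(s)) {
    cur <- subject_step(cur, sched$task_on[k], 0, 0,
                        dt = protocol$update_period)
    s[k] <- cur
  }
  s
}

# rest-end fixed point of the open-loop task/rest cycle, found by
# iterating the deterministic gain-0 map until convergence
subject_equilibrium <- function(protocol, tol = 1e-10, max_cycles = 200) {
  up <- protocol$update_period
  n_task <- as.integer(round((if (protocol$mode == "fixed") protocol$task_s
                              else mean(protocol$task_s)) / up))
  n_rest <- as.integer(round(protocol$rest_s / up))
  s <- 0
  for (cyc in seq_len(max_cycles)) {
    prev <- s
    for (k in seq_len(n_task)) s <- subject_step(s, TRUE, 0, 0, dt = up)
    for (k in seq_len(n_rest)) s <- subject_step(s, FALSE, 0, 0, dt = up)
    if (abs(s - prev) < tol) break
  }
  s
}

# per-tick task flags and block indices over a fixed protocol
tick_schedule <- function(protocol) {
  blocks <- protocol$blocks
  dur <- ifelse(is.na(blocks$duration), blocks$max, blocks$duration)
  up <- protocol$update_period
  nt <- as.integer(round(dur / up))
  task_on <- rep(blocks$kind == "TASK", times = nt)
  block <- rep(seq_len(nrow(blocks)), times = nt)
  kind <- rep(blocks$kind, times = nt)
  list(task_on = task_on, block = block, kind = kind,
       time = seq_along(task_on) * up)
}

# map a per-tick trace to one value per volume (state at volume end)
trace_per_volume <- function(trace_ticks, protocol, tr, n_vol) {
  up <- protocol$update_period
  ticks_per_vol <- tr / up
  idx <- pmin(as.integer(round(seq_len(n_vol) * ticks_per_vol)),
              length(trace_ticks))
  trace_ticks[pmax(idx, 1L)]
}
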