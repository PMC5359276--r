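#' Calibration session: CSP filters, activation ROI, baselines, targets
#'
#' Runs the full offline initialization on a simulated non-feedback
#' session with the given block design: EEG is cleaned (TR-anchored
#' gradient template subtraction, then R-peak-anchored BCG subtraction),
#' band-passed and segmented into 2 s / 95%-overlap windows labeled
#' Task/Rest to train the CSP filters; fMRI is smoothed and GLM-mapped
#' to select the most protocol-responsive activation cluster as the
#' feedback ROI. Initial baselines average the features of *all* rest
#' intervals; feedback targets are the mean task-block modulation
#' rescaled to full regulation, so a normalized value of 1 means
#' "as strong as a fully regulating subject".
#'
#' @param config a [sim_config()].
#' @param protocol a [protocol_spec()] (fixed mode).
#' @param band feature band in Hz.
#' @param fwhm spatial smoothing FWHM in mm.
#' @param n_pairs CSP filter pairs.
#' @param z_threshold,min_cluster activation-mapping parameters.
#' @param grad_buffer,bcg_buffer sliding-template capacities (TRs /
#'   pulse intervals).
#' @return an `nfb_calibration` object.
#' @export
nfb_calibrate <- function(config, protocol, band = c(8, 30), fwhm = 4,
                          n_pairs = 3L, z_threshold = 3, min_cluster = 4L,
                          grad_buffer = 10L, bcg_buffer = 15L) {
  design <- gen_task_design(protocol, config$tr)
  trace_ticks <- open_loop_trace(protocol, s0 = 0)
  nvol <- length(design$boxcar)
  trace_vol <- trace_per_volume(trace_ticks, protocol, config$tr, nvol)

  ## ---- EEG side ----
  sim <- gen_eeg(config, trace_vol, design$boxcar)
  clean <- clean_eeg_offline(sim$stream, grad_buffer, bcg_buffer)
  nch <- config$n_channels
  eeg_bp <- bandpass(clean$stream$data[seq_len(nch), , drop = FALSE],
                     band[1], band[2], fs = config$fs_eeg)
  lab <- label_windows(eeg_bp, config$fs_eeg, design$events,
                       win = 2, overlap = 0.95)
  csp <- train_csp(lab$task, lab$rest, n_pairs = n_pairs)
  f_task <- vapply(lab$task, eeg_feature, numeric(1), model = csp)
  f_rest <- vapply(lab$rest, eeg_feature, numeric(1), model = csp)
  eeg_baseline <- mean(f_rest)
  eeg_rest_sd <- sd(f_rest)
  # mean regulation over the task volumes actually used
  s_task <- mean(trace_vol[design$boxcar > 0])
  eeg_effect <- mean(-(f_task - eeg_baseline))          # ERD: drop is good
  eeg_target <- max(eeg_effect / max(s_task, 1e-6), 1e-3)

  ## ---- fMRI side ----
  fsim <- gen_fmri(config, design$boxcar, trace_vol)
  smoothed <- gaussian_smooth(fsim$series, fwhm)
  act <- activation_roi(smoothed, design$boxcar, z_threshold, min_cluster)
  bg <- background_slice(config$grid_shape)
  roi_ts <- vapply(seq_len(nvol), function(v)
    roi_mean(smoothed$data[, , , v], act$mask), numeric(1))
  bg_ts <- vapply(seq_len(nvol), function(v)
    roi_mean(smoothed$data[, , , v], bg), numeric(1))
  feat_ts <- roi_ts - bg_ts
  reg <- convolve_design(design$boxcar, hrf_double_gamma(config$tr))
  rest_vols <- reg < 0.2 * max(reg)
  task_vols <- reg > 0.7 * max(reg)
  roi_scale <- mean(roi_ts[rest_vols])                  # ~BOLD baseline
  fmri_baseline <- mean(feat_ts[rest_vols])
  fmri_apsc <- 100 * (feat_ts - fmri_baseline) / abs(roi_scale)
  s_task_vol <- mean(trace_vol[task_vols])
  fmri_target <- max(mean(fmri_apsc[task_vols]) / max(s_task_vol, 1e-6),
                     1e-3)

  structure(list(
    config = config, protocol = protocol, band = band, fwhm = fwhm,
    csp = csp,
    roi = act$mask, activation_map = act$map, background = bg,
    eeg_baseline = eeg_baseline, eeg_rest_sd = eeg_rest_sd,
    eeg_target = eeg_target,
    fmri_baseline = fmri_baseline, fmri_rest_sd = sd(feat_ts[rest_vols]),
    fmri_target = fmri_target, roi_scale = roi_scale,
    grad_buffer = grad_buffer, bcg_buffer = bcg_buffer,
    calib_features = list(eeg_task = f_task, eeg_rest = f_rest,
                          fmri_apsc = fmri_apsc, rest_vols = rest_vols)),
    class = "nfb_calibration")
}

#' @export
print.nfb_calibration <- function(x, ...) {
  cat("<nfb_calibration>\n")
  cat(sprintf("  CSP: %d filters, band [%g, %g] Hz; ROI: %d voxels\n",
              nrow(x$csp$filters), x$band[1], x$band[2],
              length(x$roi$voxels)))
  cat(sprintf("  EEG baseline %.3f (target %.3f), fMRI baseline %.3f (target %.2f%%)\n",
              x$eeg_baseline, x$eeg_target, x$fmri_baseline, x$fmri_target))
  invisible(x)
}

# offline artifact cleaning: gradient AAS on TTL anchors, then BCG AAS
# on detected R peaks
clean_eeg_offline <- function(stream, grad_buffer = 10L, bcg_buffer = 15L) {
  ttl <- stream$markers$sample[stream$markers$kind == "TTL"]
  g <- template_correct(stream, ttl, buffer = grad_buffer,
                        mode = "gradient")
  # the first TR epoch passes through uncorrected (no template yet): it
  # would dominate the detector's amplitude statistics and its pulse
  # epochs would poison the BCG template buffer, so detection starts
  # after it
  skip <- if (length(ttl) > 1L) ttl[1] + min(diff(ttl)) else 1L
  ecg_seg <- g$stream$data[nrow(g$stream$data), skip:n_samples(g$stream)]
  peaks <- detect_r_peaks(ecg_seg, fs = g$stream$fs) + skip - 1L
  b <- if (length(peaks) >= 2L)
    template_correct(g$stream, peaks, buffer = bcg_buffer, mode = "bcg")
  else list(stream = g$stream)
  list(stream = b$stream, r_peaks = peaks, grad_flagged = g$flagged)
}

# segment a band-passed matrix into windows and label each Task or Rest
# by the block that fully contains it (boundary-straddlers are dropped)
label_windows <- function(data, fs, events, win = 2, overlap = 0.95) {
  wins <- segment_windows(data, win, overlap, fs = fs)
  task_iv <- events[events$kind == "TASK", ]
  rest_iv <- events[events$kind == "REST", ]
  inside <- function(t0, t1, iv)
    any(t0 >= iv$onset_s - 1e-9 &
        t1 <= iv$onset_s + iv$duration_s + 1e-9)
  task <- list(); rest <- list()
  for (w in wins) {
    t0 <- w$start_s; t1 <- w$start_s + win
    if (nrow(task_iv) && inside(t0, t1, task_iv))
      task <- c(task, list(w$data))
    else if (nrow(rest_iv) && inside(t0, t1, rest_iv))
      rest <- c(rest, list(w$data))
  }
  list(task = task, rest = rest, windows = wins)
}

#' Run a closed-loop neurofeedback session on the simulated clock
#'
#' Drives the complete platform deterministically: the scheduler fires
#' update and protocol callbacks on the tick lattice; EEG samples and
#' BOLD volumes are generated by the subject model and absorbed with
#' their configured processing latencies; the EEG path applies online
#' gradient-template subtraction (template frozen at each TR start,
#' rebuilt from the sliding buffer when the TR completes), lazy BCG
#' subtraction at online-detected R peaks, band-pass filtering and CSP
#' band power over the most recent 2 s window; the fMRI path smooths
#' each arriving volume, extracts the background-corrected ROI mean and
#' updates the incremental GLM; both features become
#' percent-signal-change feedback against baselines re-established at
#' the end of every Rest block, are normalized to their calibration
#' targets, combined, and fed back into the subject model. All
#' randomness is drawn up-front from the run seed, so identical
#' arguments give byte-identical logs.
#'
#' @param calibration an [nfb_calibrate()] result (carries config and
#'   protocol; a different protocol may be supplied for the feedback
#'   run).
#' @param gain subject feedback gain (0 = open loop).
#' @param seed run seed (independent of the calibration seed).
#' @param protocol optional protocol overriding the calibration's.
#' @param combine `"mean"`, `"vector2d"` or `"weighted"` bimodal mode.
#' @param w EEG weight for `"weighted"`.
#' @param latency simulated processing latencies in seconds: `eeg`
#'   (amplifier-to-feature path) and `fmri` (reconstruction +
#'   processing per volume) -- features never see data newer than the
#'   tick minus these budgets.
#' @param baseline_policy per-Rest-block baseline policy, see
#'   [baseline_state()].
#' @param out_dir optional directory: event log (TSV) and feedback log
#'   (CSV) are written there atomically.
#' @return an `nfb_session` object.
#' @export
run_session <- function(calibration, gain = 0, seed = 1L,
                        protocol = NULL, combine = "mean", w = 0.5,
                        latency = list(eeg = 0.2, fmri = 0.15),
                        baseline_policy = "replace", out_dir = NULL) {
  config <- calibration$config
  if (is.null(protocol)) protocol <- calibration$protocol
  up <- protocol$update_period
  fs <- config$fs_eeg
  spt <- samples_per_tr(config)
  band <- calibration$band
  set.seed(seed + 10L)

  total_s <- protocol_duration(protocol)
  nvol <- as.integer(ceiling(total_s / config$tr))
  nsamp <- nvol * spt
  nch <- config$n_channels
  ngrad <- nch + 1L
  design <- gen_task_design(protocol, config$tr)
  boxcar <- design$boxcar
  kernel <- hrf_double_gamma(config$tr)
  reg_planned <- convolve_design(boxcar, kernel)

  ## ---- pre-drawn random material (the tick loop is RNG-free) ----
  noise_eeg <- matrix(rnorm(nch * nsamp, 0, config$noise_sd_eeg), nch, nsamp)
  rms0 <- nominal_clean_rms(config)
  r_times <- gen_r_peak_times(total_s, config$heart_rate,
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
  grad_full <- matrix(0, ngrad, nsamp)
  if (config$artifact_gain > 0) {
    tpl0 <- gradient_template(ngrad, spt, fs)
    grad_full <- tpl0[, rep(seq_len(spt), nvol), drop = FALSE] *
      (config$artifact_gain * rms0)
  }
  bcg_full <- matrix(0, ngrad, nsamp)
  pulse <- bcg_pulse(fs)
  lp <- length(pulse)
  bcg_delay <- as.integer(round(0.15 * fs))
  weights <- runif(nch, 0.5, 1) * config$bcg_amp * rms0
  for (r in r_samples) {
    idx <- (r + bcg_delay):(r + bcg_delay + lp - 1L)
    ok <- idx >= 1L & idx <= nsamp
    if (!any(ok)) next
    bcg_full[seq_len(nch), idx[ok]] <- bcg_full[seq_len(nch), idx[ok]] +
      outer(weights, pulse[ok])
  }
  n_motor <- min(2L, nch)
  osc_base <- matrix(0, n_motor, nsamp)   # unmodulated motor rhythms
  for (ch in seq_len(n_motor))
    for (f in config$osc_freqs)
      osc_base[ch, ] <- osc_base[ch, ] +
        narrowband_osc(nsamp, fs, f) * config$osc_amp / sqrt(2)
  noise_vol <- if (config$noise_sd_bold > 0)
    matrix(rnorm(prod(config$grid_shape) * nvol, 0, config$noise_sd_bold),
           prod(config$grid_shape), nvol)
  else matrix(0, prod(config$grid_shape), nvol)
  beta_flat <- {
    tb <- array(0, config$grid_shape)
    ab <- config$active_block
    tb[ab$x, ab$y, ab$z] <- config$beta
    as.vector(tb)
  }

  ## ---- mutable loop state ----
  raw_data <- matrix(NA_real_, ngrad, nsamp)   # as acquired
  gc_data <- matrix(NA_real_, ngrad, nsamp)    # gradient-corrected
  gen_upto <- 0L
  grad_buf <- template_buffer(calibration$grad_buffer, spt, ngrad)
  grad_tpl <- matrix(0, ngrad, spt)
  tr_done <- 0L
  det_peaks <- integer()
  bcg_len <- NA_integer_
  bcg_buf <- NULL
  bcg_tpl <- NULL
  bcg_pushed <- 0L
  neural <- numeric(nvol)
  vols_done <- 0L
  roi_ts <- numeric(nvol); bg_ts <- numeric(nvol)
  glm <- iglm(c("intercept", "drift", "task"))
  eeg_base <- baseline_state(calibration$eeg_baseline, "EEG",
                             policy = baseline_policy)
  fmri_base <- baseline_state(calibration$fmri_baseline, "FMRI",
                              policy = baseline_policy)
  rest_feats_eeg <- numeric(0)
  rest_vol_feats <- numeric(0)
  rest_vol_skip <- 2L                          # hemodynamic lag, volumes
  rest_vols_seen <- 0L
  s_state <- subject_equilibrium(protocol)
  last_combined <- c(0, 0)
  subj_trace <- numeric(0)

  bf_band <- signal::butter(4, band / (fs / 2), type = "pass")
  win_len <- as.integer(2 * fs)
  # pulse epochs join the template buffer only once they end this far
  # behind the acquisition head, so the template never contains samples
  # of a window it later corrects (self-subtraction would bias the band
  # power low by ~1/capacity)
  self_guard <- win_len + as.integer((latency$eeg + 0.3) * fs)
  W <- calibration$csp$filters

  update_peaks <- function() {
    # never look into the uncorrected first TR
    lookback <- max(spt + 1L, gen_upto - as.integer(6 * fs))
    if (lookback >= gen_upto) return(invisible())
    seg <- gc_data[ngrad, lookback:gen_upto]
    pk <- tryCatch(suppressWarnings(detect_r_peaks(seg, fs = fs)),
                   error = function(e) integer())
    pk <- pk + lookback - 1L
    margin <- as.integer(0.3 * fs)
    pk <- pk[pk <= gen_upto - margin & pk > spt]  # skip the raw first TR
    new <- if (length(det_peaks)) pk[pk > max(det_peaks) + margin] else pk
    det_peaks <<- c(det_peaks, sort(new))
    if (is.na(bcg_len) && length(det_peaks) >= 3L)
      bcg_len <<- as.integer(round(median(diff(det_peaks))))
    if (!is.na(bcg_len)) {
      if (is.null(bcg_buf))
        bcg_buf <<- template_buffer(calibration$bcg_buffer, bcg_len, ngrad)
      usable <- det_peaks[det_peaks + bcg_len - 1L <= gen_upto - self_guard]
      while (bcg_pushed < length(usable)) {
        p <- usable[bcg_pushed + 1L]
        bcg_buf <<- buffer_push(bcg_buf, gc_data[, p:(p + bcg_len - 1L),
                                                 drop = FALSE])
        bcg_pushed <<- bcg_pushed + 1L
      }
      bcg_tpl <<- buffer_template(bcg_buf)
    }
  }

  # generate raw samples up to index n, correcting each sub-chunk with
  # the gradient template frozen at its TR start; completed TRs rebuild
  # the template and trigger online R-peak detection
  gen_to <- function(n, task_on, s) {
    n <- min(n, nsamp)
    while (gen_upto < n) {
      epoch <- gen_upto %/% spt                # 0-based TR index
      sub_end <- min(n, (epoch + 1L) * spt)
      idx <- (gen_upto + 1L):sub_end
      chunk <- noise_eeg[, idx, drop = FALSE]
      modf <- 1 - config$erd_depth * s * as.numeric(task_on)
      chunk[seq_len(n_motor), ] <- chunk[seq_len(n_motor), , drop = FALSE] +
        modf * osc_base[, idx, drop = FALSE]
      raw <- rbind(chunk, ecg[idx]) + grad_full[, idx, drop = FALSE] +
        bcg_full[, idx, drop = FALSE]
      raw_data[, idx] <<- raw
      pos <- ((idx - 1L) %% spt) + 1L
      gc_data[, idx] <<- raw - grad_tpl[, pos, drop = FALSE]
      gen_upto <<- sub_end
      if (sub_end == (epoch + 1L) * spt) {     # TR epoch complete
        ep <- (epoch * spt + 1L):sub_end
        grad_buf <<- buffer_push(grad_buf, raw_data[, ep, drop = FALSE])
        grad_tpl <<- buffer_template(grad_buf)
        tr_done <<- epoch + 1L
        update_peaks()
      }
    }
    invisible()
  }

  # CSP band-power feature of the 2 s window ending at sample `wend`.
  # `tpl` overrides the current BCG template: retroactive evaluations
  # (the Begin-period baseline anchor) must not use a template whose
  # buffered epochs cover the window itself, or the window's own signal
  # is partially subtracted -- a bias the causally lagging steady-state
  # path never has.
  window_feature <- function(wend, tpl = bcg_tpl) {
    cols <- (wend - win_len + 1L):wend
    wdat <- bcg_correct_window(cols, tpl)[seq_len(nch), , drop = FALSE]
    wbp <- t(apply(wdat, 1, function(x)
      as.numeric(signal::filtfilt(bf_band, x))))
    eeg_feature(wbp, W)
  }

  # full-size template from the most recent buffered epochs that end
  # before `before` (same epoch count as the running template, so the
  # template-noise level matches the steady-state path)
  bcg_template_before <- function(before) {
    if (is.null(bcg_buf) || !length(bcg_buf$epochs)) return(NULL)
    usable <- det_peaks[det_peaks + bcg_len - 1L <= gen_upto - self_guard]
    in_buf <- tail(usable, length(bcg_buf$epochs))
    keep <- tail(which(in_buf + bcg_len - 1L < before), bcg_buf$capacity)
    if (length(keep) < 8L) return(NULL)
    Reduce(`+`, bcg_buf$epochs[keep]) / length(keep)
  }

  # lazy BCG subtraction over a column range of the corrected stream
  bcg_correct_window <- function(cols, tpl = bcg_tpl) {
    wdat <- gc_data[, cols, drop = FALSE]
    if (is.null(tpl)) return(wdat)
    c0 <- cols[1]; c1 <- cols[length(cols)]
    for (p in det_peaks[det_peaks <= c1 & det_peaks + bcg_len - 1L >= c0]) {
      span <- max(p, c0):min(p + bcg_len - 1L, c1)
      wdat[, span - c0 + 1L] <- wdat[, span - c0 + 1L] -
        tpl[, span - p + 1L, drop = FALSE]
    }
    wdat
  }

  absorb_volume <- function(m, task_on, s) {
    neural[m] <<- as.numeric(task_on) * s
    j <- seq_len(min(m, length(kernel)))
    reg_m <- sum(kernel[j] * neural[m - j + 1])
    vox <- config$baseline_bold + noise_vol[, m] +
      config$drift_slope * (m - 1) + beta_flat * reg_m
    volarr <- array(vox, config$grid_shape)
    volarr <- motion_correct(volarr)$volume
    volarr <- slice_time_correct(volarr)
    volarr <- gaussian_smooth(volarr, calibration$fwhm,
                              voxel_size = c(2, 2, 4))
    roi_ts[m] <<- roi_mean(volarr, calibration$roi)
    bg_ts[m] <<- roi_mean(volarr, calibration$background)
    glm <<- iglm_update(glm, design_row(m, reg_planned),
                        fmri_feature(roi_ts[m], bg_ts[m]))
    vols_done <<- m
  }

  ## ---- the tick loop ----
  sched <- start_session(protocol, first_ttl_time = 0)
  n_ticks <- as.integer(round((total_s - protocol$begin_s) / up))
  nfb_rows <- vector("list", n_ticks + 1L)
  target_fun <- function(tk) all(last_combined >= 1 - 1e-9)

  for (k in 0:n_ticks) {
    if (!sched$live) break
    now <- tick_time(protocol, k)
    adv <- scheduler_advance(sched, now, target_reached = target_fun)
    sched <- adv$state
    if (!nrow(adv$ticks)) next
    tick <- adv$ticks[1, ]
    kind <- tick$kind
    task_now <- kind == "TASK"

    # absorb acquisitions available at this tick
    gen_to(as.integer(floor(now * fs)), task_now, s_state)
    while ((vols_done + 1L) <= nvol &&
           (vols_done + 1L) * config$tr + latency$fmri <= now + 1e-9)
      absorb_volume(vols_done + 1L, task_now, s_state)

    # EEG feature over the most recent 2 s (latency-compensated)
    wend <- as.integer(floor((now - latency$eeg) * fs))
    eeg_raw <- NA_real_
    if (wend >= win_len && kind %in% c("TASK", "REST")) {
      f <- window_feature(wend)
      eeg_raw <- -(f - eeg_base$value)          # ERD: power drop is good
      # baseline features only from windows fully inside the rest
      # block, so no task-suppressed samples leak into the baseline
      if (kind == "REST" &&
          (wend - win_len) / fs >= sched$block_start - 1e-9)
        rest_feats_eeg <- c(rest_feats_eeg, f)
    }
    # fMRI feature: latest absorbed volume
    fmri_raw <- NA_real_
    if (vols_done > 0L && kind != "BEGIN") {
      feat <- fmri_feature(roi_ts[vols_done], bg_ts[vols_done])
      fmri_raw <- 100 * (feat - fmri_base$value) / abs(calibration$roi_scale)
      if (kind == "REST" && vols_done > rest_vols_seen) {
        rest_vols_seen <- vols_done
        rest_vol_feats <- c(rest_vol_feats, feat)
      }
    }
    eeg_norm <- if (is.na(eeg_raw)) NA_real_
                else normalize_for_display(eeg_raw, calibration$eeg_target)
    fmri_norm <- if (is.na(fmri_raw)) NA_real_
                 else normalize_for_display(fmri_raw, calibration$fmri_target)
    combined <- if (!is.na(eeg_norm) && !is.na(fmri_norm)) {
      smp <- combine_nfb(eeg_norm, fmri_norm, mode = combine, w = w,
                         timestamp = now)
      mean(smp$values)
    } else NA_real_
    if (!is.na(combined)) last_combined <- c(last_combined[-1], combined)

    # leaving Begin: re-anchor the EEG baseline on the last seconds of
    # the Begin period as seen by the *online* processing chain. The
    # calibration baseline comes from the offline chain, whose residual
    # artifact level differs slightly; without re-anchoring that offset
    # would bias the whole first task block.
    if (tick$transition && kind == "BEGIN") {
      ends <- wend - rev(seq(0, 8 * fs - win_len, by = fs %/% 2))
      ends <- ends[ends >= win_len]
      tpl0 <- bcg_template_before(min(ends) - win_len)
      if (length(ends) >= 5 && !is.null(tpl0)) {
        f0 <- vapply(as.integer(ends), window_feature, numeric(1),
                     tpl = tpl0)
        eeg_base <- update_baseline(eeg_base, f0)
      }
    }
    # leaving Rest: re-establish both baselines from that block
    if (tick$left_rest) {
      eeg_base <- update_baseline(eeg_base, rest_feats_eeg)
      keep <- rest_vol_feats[-seq_len(min(rest_vol_skip,
                                          length(rest_vol_feats)))]
      if (length(keep)) fmri_base <- update_baseline(fmri_base, keep)
    }
    # entering Rest: start fresh collections
    if (tick$transition && sched$current_block <= nrow(protocol$blocks) &&
        protocol$blocks$kind[sched$current_block] == "REST") {
      rest_feats_eeg <- numeric(0)
      rest_vol_feats <- numeric(0)
    }

    # the subject reacts to the feedback it just saw, under the block
    # active from this tick on; before the protocol proper starts the
    # subject idles at its resting regulation level
    kind_next <- if (sched$current_block <= nrow(protocol$blocks))
      protocol$blocks$kind[sched$current_block] else "END"
    if (kind_next != "BEGIN")
      s_state <- subject_step(s_state, kind_next == "TASK",
                              nfb = if (is.na(combined)) 0 else combined,
                              gain = gain, dt = up)
    subj_trace <- c(subj_trace, s_state)

    nfb_rows[[k + 1L]] <- data.frame(
      tick = tick$tick, time_s = now, block = tick$block, kind = kind,
      eeg_raw = eeg_raw, eeg_baseline = eeg_base$value, eeg_norm = eeg_norm,
      fmri_raw = fmri_raw, fmri_baseline = fmri_base$value,
      fmri_norm = fmri_norm, combined = combined,
      subject_state = s_state,
      eeg_window_end_s = if (wend >= win_len) wend / fs else NA_real_,
      fmri_volume = vols_done)
  }
  nfb <- do.call(rbind, nfb_rows[!vapply(nfb_rows, is.null, logical(1))])
  rownames(nfb) <- NULL

  ttl_times <- (seq_len(vols_done) - 1L) * config$tr
  reports <- check_sync(sched, ttl_times, config$tr)
  session <- structure(list(
    config = config, protocol = protocol, gain = gain, seed = seed,
    combine = combine, calibration = calibration,
    nfb = nfb, events = sched$events, sync_reports = reports,
    scheduler = sched, subject_trace = subj_trace,
    roi_ts = roi_ts[seq_len(vols_done)], bg_ts = bg_ts[seq_len(vols_done)],
    glm = glm, r_peaks_true = r_samples, r_peaks_detected = det_peaks,
    latency = latency), class = "nfb_session")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_atomic(sched$events, file.path(out_dir, "event_log.tsv"))
    write_nfb_log(session_nfb_log(session), file.path(out_dir, "nfb_log.csv"))
  }
  session
}

# long-format tidy feedback log: one row per tick and modality
session_nfb_log <- function(session) {
  n <- session$nfb
  long <- rbind(
    data.frame(time_s = n$time_s, block = n$block, modality = "EEG",
               raw = n$eeg_raw, baseline = n$eeg_baseline,
               normalized = n$eeg_norm, combined = n$combined),
    data.frame(time_s = n$time_s, block = n$block, modality = "FMRI",
               raw = n$fmri_raw, baseline = n$fmri_baseline,
               normalized = n$fmri_norm, combined = n$combined))
  long[order(long$time_s, long$modality), ]
}

#' @export
print.nfb_session <- function(x, ...) {
  cat(sprintf("<nfb_session> gain %g, seed %d, %d ticks, %d volumes, %s\n",
              x$gain, x$seed, nrow(x$nfb), length(x$roi_ts),
              if (x$scheduler$aborted) "ABORTED" else "complete"))
  invisible(x)
}

#' @export
summary.nfb_session <- function(object, ...) {
  n <- object$nfb
  task <- n[n$kind == "TASK" & !is.na(n$combined), ]
  rest <- n[n$kind == "REST" & !is.na(n$combined), ]
  blocks <- unique(task$block)
  per_block <- vapply(blocks, function(b)
    mean(task$combined[task$block == b]), numeric(1))
  est <- tryCatch(iglm_estimates(object$glm), error = function(e) NULL)
  out <- list(mean_task_nfb = mean(task$combined),
              mean_rest_nfb = if (nrow(rest)) mean(rest$combined) else NA,
              task_block_means = per_block,
              first_task_block = per_block[1],
              last_task_block = per_block[length(per_block)],
              glm_task_t = if (!is.null(est)) est$t[1, 1] else NA,
              sync_reports = nrow(object$sync_reports),
              aborted = object$scheduler$aborted)
  class(out) <- "summary.nfb_session"
  out
}

#' @export
print.summary.nfb_session <- function(x, ...) {
  cat("Closed-loop session summary\n")
  cat(sprintf("  mean normalized NFB: task %.3f, rest %.3f\n",
              x$mean_task_nfb, x$mean_rest_nfb))
  cat("  task-block means:",
      paste(sprintf("%.3f", x$task_block_means), collapse = " "), "\n")
  cat(sprintf("  ROI GLM task t = %.2f; %d sync report(s)%s\n",
              x$glm_task_t, x$sync_reports,
              if (x$aborted) "; session ABORTED" else ""))
  invisible(x)
}

#' @export
plot.nfb_session <- function(x, ...) {
  n <- x$nfb
  ok <- !is.na(n$combined)
  graphics::plot(n$time_s[ok], n$combined[ok], type = "l",
                 xlab = "time (s)", ylab = "normalized NFB",
                 main = sprintf("gain %g", x$gain), ylim = c(0, 1), ...)
  graphics::lines(n$time_s, n$subject_state, col = "grey50", lty = 2)
  graphics::rug(n$time_s[n$kind == "TASK"], col = "red")
  invisible(x)
}
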