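test_that("task design boxcar matches the block structure", {
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 2, begin_s = 0)
  d <- gen_task_design(pr, tr = 2)
  expect_length(d$boxcar, 40)
  expect_equal(d$boxcar, rep(rep(c(1, 0), each = 10), 2))
  expect_equal(d$events$kind, rep(c("TASK", "REST"), 2))
  expect_equal(d$events$onset_s, c(0, 20, 40, 60))

  pr3 <- protocol_spec(task_s = 6, rest_s = 4, n_blocks = 3, begin_s = 0)
  d3 <- gen_task_design(pr3, tr = 2)
  expect_length(d3$boxcar, 15)
  expect_equal(d3$events$onset_s[d3$events$kind == "TASK"], c(0, 10, 20))
  expect_equal(d3$boxcar, rep(c(1, 1, 1, 0, 0), 3))
})

test_that("task design: empty protocol and non-multiple durations", {
  pr0 <- protocol_spec(n_blocks = 0, begin_s = 0)
  d0 <- gen_task_design(pr0, tr = 2)
  expect_length(d0$boxcar, 0)
  expect_equal(nrow(d0$events), 0L)

  pr_bad <- protocol_spec(task_s = 5, rest_s = 5, n_blocks = 1, begin_s = 0)
  expect_error(gen_task_design(pr_bad, tr = 2), "multiple of TR")
})

test_that("EEG generator: exact decomposition and artifact scaling", {
  cfg <- tiny_config()
  pr <- tiny_protocol()
  d <- gen_task_design(pr, cfg$tr)
  sim <- gen_eeg(cfg, subject_trace = 1, design = d$boxcar)
  with(sim$truth, expect_equal(
    sim$stream$data, clean_eeg + gradient_component + bcg_component,
    tolerance = 1e-12))
  ratio <- sqrt(mean(sim$truth$gradient_component^2)) /
    sqrt(mean(sim$truth$clean_eeg^2))
  expect_equal(ratio, cfg$artifact_gain, tolerance = 0.01)
})

test_that("EEG generator: gain-zero and fixed-rate heartbeat cases", {
  cfg <- tiny_config(artifact_gain = 0, erd_depth = 0)
  sim <- gen_eeg(cfg)
  expect_true(all(sim$truth$gradient_component == 0))
  expect_equal(sim$stream$data,
               sim$truth$clean_eeg + sim$truth$bcg_component)

  cfg60 <- tiny_config(heart_rate = 60, heart_jitter_sd = 0)
  sim60 <- gen_eeg(cfg60)
  expect_true(all(diff(sim60$truth$r_peak_samples) == cfg60$fs_eeg))
})

test_that("EEG generator is deterministic for identical configs", {
  a <- gen_eeg(tiny_config(seed = 11))
  b <- gen_eeg(tiny_config(seed = 11))
  expect_identical(a$stream$data, b$stream$data)
  expect_identical(a$truth$r_peak_samples, b$truth$r_peak_samples)
})

test_that("motor-channel band power drops during task (ERD)", {
  cfg <- tiny_config(seed = 21, artifact_gain = 0, bcg_amp = 0,
                     erd_depth = 0.6)
  pr <- tiny_protocol(begin_s = 0)
  d <- gen_task_design(pr, cfg$tr)
  sim <- gen_eeg(cfg, subject_trace = 1, design = d$boxcar)
  spt <- cfg$fs_eeg * cfg$tr
  task_idx <- unlist(lapply(which(d$boxcar > 0),
                            function(v) ((v - 1) * spt + 1):(v * spt)))
  rest_idx <- setdiff(seq_len(ncol(sim$stream$data)), task_idx)
  bp <- bandpass(sim$stream$data[1:2, , drop = FALSE], 8, 30,
                 fs = cfg$fs_eeg)
  expect_lt(mean(bp[, task_idx]^2), mean(bp[, rest_idx]^2))
})

test_that("BOLD generator: null, convolution oracle and pure drift", {
  pr <- tiny_protocol(begin_s = 0)
  d <- gen_task_design(pr, 2)
  nv <- length(d$boxcar)
  cfg0 <- tiny_config(noise_sd_bold = 0, drift_slope = 0, beta = 0,
                      n_volumes = nv)
  f0 <- gen_fmri(cfg0, d$boxcar, 1)
  expect_true(all(f0$series$data == cfg0$baseline_bold))

  cfg1 <- tiny_config(noise_sd_bold = 0, drift_slope = 0, beta = 1,
                      n_volumes = nv)
  f1 <- gen_fmri(cfg1, d$boxcar, 1)
  # independent brute-force discrete convolution
  h <- hrf_double_gamma(2)
  oracle <- numeric(nv)
  for (k in seq_len(nv))
    for (j in seq_along(h))
      if (k - j + 1 >= 1) oracle[k] <- oracle[k] + h[j] * d$boxcar[k - j + 1]
  vox <- f1$truth$active_mask[1]
  series <- sapply(seq_len(nv), function(v) f1$series$data[, , , v][vox])
  expect_equal(series, cfg1$baseline_bold + oracle, tolerance = 1e-12)

  cfgd <- tiny_config(noise_sd_bold = 0, drift_slope = 0.5, beta = 0,
                      n_volumes = nv)
  fd <- gen_fmri(cfgd, d$boxcar, 1)
  v1 <- sapply(seq_len(nv), function(v) fd$series$data[1, 1, 1, v])
  expect_equal(v1, cfgd$baseline_bold + 0.5 * (seq_len(nv) - 1))
})

test_that("background slice carries no task signal", {
  pr <- tiny_protocol(begin_s = 0)
  d <- gen_task_design(pr, 2)
  cfg <- tiny_config(noise_sd_bold = 0, drift_slope = 0.5,
                     n_volumes = length(d$boxcar))
  f <- gen_fmri(cfg, d$boxcar, 1)
  top <- background_slice <- hybridnf:::background_slice(cfg$grid_shape)
  top_mean <- sapply(seq_len(length(d$boxcar)), function(v)
    mean(f$series$data[, , , v][top]))
  resid <- detrend(top_mean, "linear")
  expect_lt(max(abs(resid)), 1e-9)
  # an active voxel retains task variance after the same detrend
  act <- sapply(seq_len(length(d$boxcar)), function(v)
    f$series$data[, , , v][f$truth$active_mask[1]])
  expect_gt(max(abs(detrend(act, "linear"))), 0.1)
})

test_that("subject model: open loop, saturation and gain monotonicity", {
  # gain 0: trajectory independent of the feedback stream
  s_a <- s_b <- 0.2
  for (k in 1:40) {
    s_a <- subject_step(s_a, TRUE, nfb = 1, gain = 0)
    s_b <- subject_step(s_b, TRUE, nfb = -1, gain = 0)
  }
  expect_identical(s_a, s_b)

  expect_lte(subject_step(1, TRUE, nfb = 1, gain = 1), 1)
  expect_gte(subject_step(0, FALSE, nfb = -1, gain = 1), 0)

  # direct simulation: positive feedback with gain accelerates learning
  s0 <- s5 <- 0
  for (k in 1:40) {
    s0 <- subject_step(s0, TRUE, nfb = 0.8, gain = 0)
    s5 <- subject_step(s5, TRUE, nfb = 0.8, gain = 0.5)
  }
  expect_gte(s5, s0)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(fs_eeg = 250, tr = 2.001), "integer")
  expect_error(sim_config(erd_depth = 1.5), "erd_depth")
  expect_error(sim_config(artifact_gain = -1), "artifact_gain")
  expect_error(sim_config(grid_shape = c(12, 12)), "grid_shape")
  expect_error(sim_config(active_block = list(x = 5:7, y = 5:7, z = 6L)),
               "background")
})
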