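test_that("R peaks are recovered on synthetic ECG", {
  cfg <- tiny_config(seed = 2, artifact_gain = 0, bcg_amp = 0,
                     heart_rate = 60, heart_jitter_sd = 0, n_volumes = 30)
  sim <- gen_eeg(cfg)
  pk <- detect_r_peaks(sim$stream)
  truth <- sim$truth$r_peak_samples
  expect_equal(length(pk), length(truth))
  # recall 1.0 within a small constant alignment offset
  off <- vapply(truth, function(p) min(abs(pk - p)), numeric(1))
  expect_true(all(off <= 6))
})

test_that("degenerate ECG inputs are handled gracefully", {
  expect_warning(pk <- detect_r_peaks(rep(0, 1000), fs = 250), "flat")
  expect_length(pk, 0)
  expect_error(detect_r_peaks(rep(0, 10), fs = 250), "shorter")
})

test_that("two beats inside the refractory window keep only the stronger", {
  fs <- 250
  x <- rnorm(2000, sd = 1e-4)
  sp <- hybridnf:::ecg_spike(fs)
  put <- function(x, at, amp) {
    idx <- at:(at + length(sp) - 1L)
    x[idx] <- x[idx] + amp * sp
    x
  }
  x <- put(x, 500, 1)
  x <- put(x, 540, 0.5)   # 0.16 s later: inside the 0.3 s refractory
  x <- put(x, 1500, 1)
  pk <- detect_r_peaks(x, fs = fs)
  expect_length(pk, 2)
  expect_true(all(abs(pk - c(500, 1500)) <= length(sp)))
})

test_that("constant epoch-periodic artifacts are annihilated exactly", {
  fs <- 250
  n_epochs <- 8
  L <- 100L
  art <- sin(seq_len(L) / 7) * 50
  data <- matrix(rep(art, n_epochs), nrow = 2, ncol = L * n_epochs,
                 byrow = TRUE)
  st <- eeg_stream(data, fs)
  anchors <- seq(1L, L * n_epochs, by = L)
  out <- template_correct(st, anchors, buffer = 10, mode = "gradient")
  # first epoch passes through raw and is flagged
  expect_true(anchors[1] %in% out$flagged)
  expect_equal(out$stream$data[, 1:L], data[, 1:L])
  # every later epoch cancels to machine precision, any buffer fill
  expect_equal(max(abs(out$stream$data[, (L + 1):(L * n_epochs)])), 0)
})

test_that("template correction is linear in the input", {
  fs <- 100
  set.seed(42)
  x <- matrix(rnorm(2 * 600), 2)
  y <- matrix(rnorm(2 * 600), 2)
  anchors <- seq(1L, 600L, by = 100L)
  cx <- template_correct(eeg_stream(x, fs), anchors, buffer = 4)$stream$data
  cy <- template_correct(eeg_stream(y, fs), anchors, buffer = 4)$stream$data
  cxy <- template_correct(eeg_stream(x + y, fs), anchors,
                          buffer = 4)$stream$data
  expect_equal(cxy, cx + cy, tolerance = 1e-12)
})

test_that("gradient artifacts are suppressed by >= 30 dB at default gain", {
  cfg <- tiny_config(seed = 5, n_volumes = 40)
  sim <- gen_eeg(cfg)
  st <- sim$stream
  ttl <- st$markers$sample[st$markers$kind == "TTL"]
  out <- template_correct(st, ttl, buffer = 10, mode = "gradient")
  spt <- cfg$fs_eeg * cfg$tr
  post <- (10 * spt + 1):ncol(st$data)    # after the sliding buffer fills
  resid <- out$stream$data[, post] - sim$truth$clean_eeg[, post] -
    sim$truth$bcg_component[, post]
  supp <- mean(resid^2) / mean(sim$truth$gradient_component[, post]^2)
  expect_lt(10 * log10(supp), -30)
})

test_that("irregular anchors raise a desync error in gradient mode", {
  st <- eeg_stream(matrix(0, 1, 1000), 250)
  expect_error(template_correct(st, c(1, 101, 210), mode = "gradient"),
               "desync")
  # same spacing is fine in bcg mode
  expect_silent(template_correct(st, c(1, 101, 210), mode = "bcg"))
})

test_that("BCG subtraction restores the clean EEG (fixed rate)", {
  cfg <- tiny_config(seed = 5, artifact_gain = 0, heart_rate = 60,
                     heart_jitter_sd = 0, n_volumes = 40)
  sim <- gen_eeg(cfg)
  pk <- detect_r_peaks(sim$stream)
  out <- template_correct(sim$stream, pk, buffer = 15, mode = "bcg")
  seg <- 6000:ncol(sim$stream$data)       # past the 15-beat warm-up
  cors <- vapply(1:cfg$n_channels, function(ch)
    cor(out$stream$data[ch, seg], sim$truth$clean_eeg[ch, seg]),
    numeric(1))
  expect_true(all(cors >= 0.95))
})

test_that("band-pass keeps in-band and rejects out-of-band tones", {
  fs <- 250
  t <- (0:2499) / fs
  mid <- 500:2000
  in_band <- bandpass(sin(2 * pi * 20 * t), 8, 30, fs = fs)
  expect_gte(max(abs(in_band[mid])), 0.95)
  out_band <- bandpass(sin(2 * pi * 2 * t), 8, 30, fs = fs)
  expect_lte(max(abs(out_band[mid])), 0.05)
  expect_equal(bandpass(rep(0, 1000), 8, 30, fs = fs), rep(0, 1000))
  expect_error(bandpass(rnorm(100), 30, 8, fs = fs), "invalid band")
  expect_error(bandpass(rnorm(100), 8, 200, fs = fs), "invalid band")
})

test_that("window segmentation: overlap arithmetic and edge cases", {
  fs <- 250
  data <- matrix(rnorm(2 * 20 * fs), 2)
  w <- segment_windows(data, win = 2, overlap = 0.95, fs = fs)
  expect_length(w, 181)
  starts <- vapply(w, `[[`, numeric(1), "start_s")
  expect_equal(starts, seq(0, 18, by = 0.1))

  expect_length(segment_windows(matrix(0, 1, 4 * fs), 2, 0, fs = fs), 2)
  expect_length(segment_windows(matrix(0, 1, 475), 2, 0, fs = fs), 0)
})

test_that("window count matches brute-force enumeration", {
  fs <- 100
  set.seed(9)
  for (i in 1:20) {
    T_s <- sample(3:30, 1)
    L_s <- sample(1:3, 1)
    o <- sample(c(0, 0.5, 0.75, 0.9), 1)
    w <- segment_windows(matrix(0, 1, T_s * fs), L_s, o, fs = fs)
    oracle <- enumerate_windows(T_s * fs, L_s * fs,
                                max(round(L_s * fs * (1 - o)), 1))
    expect_length(w, length(oracle))
  }
})
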