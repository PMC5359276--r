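test_that("percent signal change arithmetic and scale invariance", {
  expect_equal(apsc(10, 10), 0)
  expect_equal(apsc(12, 10), 20)
  expect_equal(apsc(8, 10), -20)
  # ratio variant is invariant under joint rescaling
  set.seed(1)
  for (i in 1:20) {
    f <- runif(1, -5, 5); b <- runif(1, 0.5, 5); k <- runif(1, 0.1, 10)
    expect_equal(apsc(k * f, k * b), apsc(f, b), tolerance = 1e-10)
  }
  expect_error(apsc(1, 0), "difference")
  expect_equal(apsc(1.2, 1, variant = "difference", scale = 10), 2)
})

test_that("z-score feedback and its degenerate guard", {
  expect_equal(zscore_feedback(5, 5, 2), 0)
  expect_equal(zscore_feedback(9, 5, 2), 2)
  expect_error(zscore_feedback(1, 0, 0), "rest_sd")
  # recomputing rest z over the calibration rest set centers it at 0
  cal <- shared_calibration()
  fr <- cal$calib_features$eeg_rest
  z <- zscore_feedback(fr, mean(fr), sd(fr))
  expect_lt(abs(mean(z)), 1e-10)
})

test_that("ROI-size feedback", {
  expect_equal(roi_size_change(10, 10), 0)
  expect_equal(roi_size_change(15, 10), 50)
  expect_equal(roi_size_change(5, 10), -50)
  expect_error(roi_size_change(5, 0), "baseline")
})

test_that("baseline updates: replacement, cumulative and guards", {
  b <- baseline_state(2, "EEG", policy = "replace")
  b <- update_baseline(b, rep(5, 10))
  expect_equal(b$value, 5)
  b2 <- update_baseline(b, rep(5, 10))          # identical block: no move
  expect_equal(b2$value, 5)
  b3 <- update_baseline(b2, rep(8, 10))
  expect_equal(b3$value, 8)

  bc <- baseline_state(2, "FMRI", policy = "cumulative")
  bc <- update_baseline(bc, rep(4, 5))
  bc <- update_baseline(bc, rep(8, 5))
  expect_equal(bc$value, 6)

  expect_warning(bu <- update_baseline(b3, numeric()), "empty")
  expect_equal(bu$value, b3$value)
})

test_that("bimodal combination modes", {
  s <- combine_nfb(0.4, 0.6, mode = "mean")
  expect_equal(s$values, 0.5)
  sw <- combine_nfb(0.4, 0.6, mode = "weighted", w = 1)
  expect_equal(sw$values, 0.4)
  v <- combine_nfb(0.3, 0.9, mode = "vector2d")
  expect_equal(unname(v$values), c(0.3, 0.9))
  expect_equal(names(v$values), c("EEG", "FMRI"))
  expect_error(combine_nfb(0.4, NULL, mode = "mean"), "fMRI")
  expect_error(combine_nfb(NULL, NULL), "no feedback")
  # unimodal passthrough
  u <- combine_nfb(eeg_nfb = 0.7)
  expect_equal(u$values, 0.7)
  expect_equal(u$modalities, "EEG")
})

test_that("display normalization: bounds, monotonicity, idempotence", {
  expect_equal(normalize_for_display(2, target = 2), 1)
  expect_equal(normalize_for_display(0, target = 2), 0)
  expect_equal(normalize_for_display(1, target = 2), 0.5)
  expect_equal(normalize_for_display(-3, target = 2), 0)   # clamped
  expect_equal(normalize_for_display(9, target = 2), 1)    # clamped
  x <- seq(-1, 3, by = 0.1)
  y <- normalize_for_display(x, target = 2)
  expect_true(all(diff(y) >= 0))
  # fixed points of the unit interval under target 1
  expect_equal(normalize_for_display(c(0, 1), target = 1), c(0, 1))
  expect_error(normalize_for_display(1, target = 0, floor = 0), "target")
})

test_that("combined mean feedback is bounded by its inputs", {
  set.seed(4)
  for (i in 1:20) {
    e <- runif(1); f <- runif(1)
    m <- combine_nfb(e, f, mode = "mean")$values
    expect_gte(m, min(e, f))
    expect_lte(m, max(e, f))
    w <- runif(1)
    expect_equal(combine_nfb(e, f, "weighted", w = w)$values,
                 w * e + (1 - w) * f)
  }
})
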