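test_that("Gaussian smoothing: identity, constants and impulse peak", {
  vol <- array(rnorm(12 * 12 * 6), c(12, 12, 6))
  expect_identical(gaussian_smooth(vol, 0), vol)

  const <- array(3.5, c(8, 8, 4))
  expect_equal(gaussian_smooth(const, 5), const, tolerance = 1e-12)

  # unit impulse, isotropic 2 mm voxels, fwhm chosen so sigma = 1 voxel
  imp <- array(0, c(11, 11, 11))
  imp[6, 6, 6] <- 1
  sm <- gaussian_smooth(imp, fwhm = 2.3548 * 2, voxel_size = c(2, 2, 2))
  # closed-form: product of the three normalized discrete kernel centers
  r <- ceiling(3 * 1)
  k <- exp(-(-r:r)^2 / 2)
  k <- k / sum(k)
  expect_equal(sm[6, 6, 6], k[r + 1]^3, tolerance = 1e-12)
})

test_that("ROI mean and the empty-mask guard", {
  vol <- array(7, c(4, 4, 2))
  expect_equal(roi_mean(vol, 1:5), 7)
  vol[1] <- 1; vol[2] <- 3
  expect_equal(roi_mean(vol, 1:2), 2)
  expect_error(roi_mean(vol, integer()), "empty ROI")
  m <- roi_mask(1:3, c(4, 4, 2))
  expect_equal(roi_mean(vol, m), mean(vol[1:3]))
})

test_that("detrending: exact line, EMA warm-up, causal variant", {
  k <- 0:19
  y <- 3 + 0.5 * k
  expect_equal(detrend(y, "linear"), rep(0, 20), tolerance = 1e-12)

  const <- rep(4, 15)
  r <- detrend(const, "ema", alpha = 0.3)
  expect_equal(r, rep(0, 15))
  expect_equal(r[1], 0)

  yc <- 1 + 0.5 * (0:29)
  rc <- detrend(yc, "linear", causal = TRUE)
  expect_lt(max(abs(rc[10:30])), 1e-6)
})

test_that("incremental GLM: single-scan algebra and order invariance", {
  st <- iglm(c("a", "b"))
  st <- iglm_update(st, c(1, 2), 3)
  expect_equal(st$n, 1L)
  expect_equal(st$xtx, outer(c(1, 2), c(1, 2)))
  expect_equal(drop(st$xty), c(3, 6))
  expect_equal(st$yty, 9)

  set.seed(1)
  X <- cbind(1, rnorm(10))
  y <- rnorm(10)
  perm <- sample(10)
  s1 <- s2 <- iglm(c("i", "x"))
  for (k in 1:10) s1 <- iglm_update(s1, X[k, ], y[k])
  for (k in perm) s2 <- iglm_update(s2, X[k, ], y[k])
  expect_equal(s1$xtx, s2$xtx, tolerance = 1e-12)
  expect_equal(s1$xty, s2$xty, tolerance = 1e-12)
})

test_that("incremental estimates equal batch least squares on prefixes", {
  set.seed(2)
  n <- 60
  X <- cbind(1, seq_len(n), rnorm(n))
  y <- X %*% c(2, -0.1, 1.5) + rnorm(n, sd = 0.3)
  st <- iglm(c("i", "drift", "task"))
  for (k in seq_len(n)) {
    st <- iglm_update(st, X[k, ], y[k])
    if (k > 4) {
      est <- iglm_estimates(st)
      oracle <- batch_ols(X[1:k, , drop = FALSE], y[1:k])
      expect_equal(drop(est$betas), oracle$beta, tolerance = 1e-8)
      expect_equal(drop(est$sigma2), oracle$sigma2, tolerance = 1e-8)
    }
  }
})

test_that("noise-free fits are exact; singular designs are named", {
  st <- iglm(c("x"))
  for (k in 1:10) st <- iglm_update(st, k, 2 * k)
  est <- iglm_estimates(st)
  expect_equal(drop(est$betas), 2, tolerance = 1e-12)
  expect_equal(drop(est$sigma2), 0, tolerance = 1e-12)

  st2 <- iglm(c("a", "a_copy"))
  for (k in 1:10) st2 <- iglm_update(st2, c(k, k), rnorm(1))
  expect_error(iglm_estimates(st2), "a_copy")
  expect_message(iglm_estimates(st2, ridge = 1e-6), "ridge")
})

test_that("activation mapping recovers the active block", {
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 4, begin_s = 0)
  d <- gen_task_design(pr, 2)
  cfg <- tiny_config(seed = 31, n_volumes = length(d$boxcar))
  f <- gen_fmri(cfg, d$boxcar, 1)
  act <- activation_roi(f$series, d$boxcar, z_threshold = 3,
                        min_cluster = 4)
  expect_gte(jaccard(act$mask$voxels, f$truth$active_mask), 0.8)
  expect_equal(act$map$df, length(d$boxcar) - 3L)
})

test_that("null data yield the no-cluster error", {
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 3, begin_s = 0)
  d <- gen_task_design(pr, 2)
  cfg <- tiny_config(seed = 32, beta = 0, n_volumes = length(d$boxcar))
  f <- gen_fmri(cfg, d$boxcar, 1)
  expect_error(activation_roi(f$series, d$boxcar, 3, 4), "threshold")
})

test_that("the stronger of two blobs wins; shifts are equivariant", {
  gs <- c(10, 10, 4)
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 3, begin_s = 0)
  d <- gen_task_design(pr, 2)
  nv <- length(d$boxcar)
  reg <- hybridnf:::convolve_design(d$boxcar, hrf_double_gamma(2))
  build <- function(blob_ix, betas, seed) {
    set.seed(seed)
    base <- array(100, c(gs, nv)) +
      array(rnorm(prod(gs) * nv, sd = 0.05), c(gs, nv))
    for (i in seq_along(blob_ix))
      for (v in seq_len(nv)) {
        vol <- base[, , , v]
        vol[blob_ix[[i]]] <- vol[blob_ix[[i]]] + betas[i] * reg[v]
        base[, , , v] <- vol
      }
    volume_series(base, 2)
  }
  blob <- function(x0, y0, z0) {
    as.vector(outer(outer(x0 + (0:1), (y0 + (0:1) - 1) * gs[1], "+"),
                    (z0 + (0:0) - 1) * gs[1] * gs[2], "+"))
  }
  b1 <- blob(2, 2, 2); b2 <- blob(7, 7, 3)
  two <- build(list(b1, b2), c(2, 1), seed = 33)
  act <- activation_roi(two, d$boxcar, 3, 3)
  expect_setequal(act$mask$voxels, b1)

  sh1 <- build(list(b1), 2, seed = 34)
  sh2 <- build(list(b2), 2, seed = 34)
  a1 <- activation_roi(sh1, d$boxcar, 3, 3)
  a2 <- activation_roi(sh2, d$boxcar, 3, 3)
  expect_setequal(a1$mask$voxels, b1)
  expect_setequal(a2$mask$voxels, b2)
})

test_that("fMRI feature modes behave as specified", {
  expect_equal(fmri_feature(5, 5, "background_subtracted"), 0)
  expect_equal(fmri_feature(42, mode = "raw"), 42)
  # global multiplicative drift with no activation: both regions share
  # the baseline, so the subtracted feature stays constant at zero
  g <- 1 + 0.01 * (0:9)
  feats <- vapply(g, function(gt)
    fmri_feature(100 * gt, 100 * gt), numeric(1))
  expect_true(all(feats == 0))
})

test_that("preprocessing stubs pass data through unchanged", {
  vol <- array(rnorm(60), c(5, 4, 3))
  mc <- motion_correct(vol)
  expect_identical(mc$volume, vol)
  expect_equal(mc$motion_params, rep(0, 6))
  expect_identical(slice_time_correct(vol), vol)
})
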