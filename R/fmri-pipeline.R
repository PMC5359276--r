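#' Separable Gaussian spatial smoothing
#'
#' Convolves each axis with a truncated, renormalized Gaussian kernel
#' (sigma = fwhm / 2.3548, converted from mm to voxels through the
#' affine's voxel sizes). Edges use replicate padding, so constant
#' fields are preserved exactly. `fwhm = 0` is the identity.
#'
#' @param volume 3D array, or a [volume_series()] (every volume is
#'   smoothed).
#' @param fwhm full width at half maximum in mm (scalar, isotropic).
#' @param voxel_size voxel edge lengths in mm per axis (taken from the
#'   series affine when available).
#' @return same type as the input.
#' @export
gaussian_smooth <- function(volume, fwhm, voxel_size = c(2, 2, 4)) {
  stopifnot(fwhm >= 0)
  if (inherits(volume, "volume_series")) {
    voxel_size <- abs(diag(volume$affine)[1:3])
    for (v in seq_len(n_volumes(volume)))
      volume$data[, , , v] <- gaussian_smooth(volume$data[, , , v], fwhm,
                                              voxel_size)
    return(volume)
  }
  if (fwhm == 0) return(volume)
  sigma_vox <- (fwhm / 2.3548) / voxel_size
  out <- volume
  for (ax in 1:3) {
    k <- gauss_kernel_1d(sigma_vox[ax])
    if (length(k) > 1L) out <- conv_axis_replicate(out, k, ax)
  }
  out
}

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve one axis of a 3D array with kernel k, replicate padding
conv_axis_replicate <- function(arr, k, axis) {
  r <- (length(k) - 1L) %/% 2L
  conv1 <- function(x) {
    xp <- c(rep(x[1], r), x, rep(x[length(x)], r))
    out <- numeric(length(x))
    for (i in seq_along(x)) out[i] <- sum(k * xp[i:(i + 2L * r)])
    out
  }
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- apply(m, 2, conv1)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

#' Mean BOLD over a region of interest
#'
#' @param volume 3D array (one volume).
#' @param mask a [roi_mask()] or integer vector of linear voxel indices.
#' @return scalar mean; an empty mask is an error (it signals a bad
#'   calibration, not a recoverable state).
#' @export
roi_mean <- function(volume, mask) {
  voxels <- if (inherits(mask, "roi_mask")) mask$voxels else as.integer(mask)
  if (!length(voxels)) stop("empty ROI mask: recalibrate before extracting feedback",
                            call. = FALSE)
  mean(volume[voxels])
}

# linear indices of the top (background) slice of a grid
background_slice <- function(grid_shape) {
  nxy <- grid_shape[1] * grid_shape[2]
  (grid_shape[3] - 1L) * nxy + seq_len(nxy)
}

#' Remove scanner drift from a voxel/ROI time series
#'
#' `method = "linear"` subtracts the least-squares line; with
#' `causal = TRUE` the line is refit on the growing series at each scan
#' and only the newest point's residual is causal output (the real-time
#' variant). `method = "ema"` subtracts a running exponential moving
#' average with smoothing `alpha` (initialized at the first value, so
#' the first residual is 0).
#'
#' @param series numeric vector.
#' @param method `"linear"` or `"ema"`.
#' @param alpha EMA smoothing in (0, 1].
#' @param causal for `"linear"`: refit per scan on past data only.
#' @return residual series, same length.
#' @export
detrend <- function(series, method = c("linear", "ema"), alpha = 0.2,
                    causal = FALSE) {
  method <- match.arg(method)
  n <- length(series)
  if (method == "linear") {
    if (n < 2L) stop("linear detrending needs at least 2 scans",
                     call. = FALSE)
    if (!causal) {
      k <- seq_len(n)
      fit <- lsfit(k, series)
      return(unname(fit$residuals))
    }
    out <- numeric(n)
    out[1] <- 0
    for (m in 2:n) {
      k <- seq_len(m)
      cf <- lsfit(k, series[k])$coefficients
      out[m] <- series[m] - (cf[1] + cf[2] * m)
    }
    return(out)
  }
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  ema <- numeric(n)
  ema[1] <- series[1]
  for (m in seq_len(n)[-1]) ema[m] <- alpha * series[m] + (1 - alpha) * ema[m - 1]
  series - ema
}

#' Per-volume fMRI feature
#'
#' @param roi_signal scalar ROI mean of the current volume.
#' @param background_signal scalar background-region mean (top slice).
#' @param mode `"raw"` returns the ROI signal; `"background_subtracted"`
#'   removes the global signal so scanner-wide drifts cancel.
#' @return scalar feature.
#' @export
fmri_feature <- function(roi_signal, background_signal = NULL,
                         mode = c("background_subtracted", "raw")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(roi_signal))
  if (mode == "raw") return(roi_signal)
  stopifnot(is.finite(background_signal))
  roi_signal - background_signal
}

#' Motion-correction stub
#'
#' Interface slot for rigid-body realignment: returns the input volume
#' unchanged together with six zero motion parameters. Real realignment
#' is delegated to external tooling in a hardware deployment.
#' @param volume 3D array.
#' @return list(volume, motion_params).
#' @export
motion_correct <- function(volume) {
  list(volume = volume, motion_params = rep(0, 6))
}

#' Slice-time correction stub
#'
#' Pass-through interface slot; see [motion_correct()].
#' @param volume 3D array.
#' @return the input volume.
#' @export
slice_time_correct <- function(volume) volume
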