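#' Average percent signal change
#'
#' The feedback statistic: relative change of the current feature
#' against its rest baseline. The ratio variant
#' `100 * (feature - baseline) / |baseline|` suits positive-scale
#' signals such as ROI BOLD; log-domain EEG band-power features use the
#' difference variant `scale * (feature - baseline)` (a ratio of log
#' powers is meaningless). Increase maps to positive in either variant.
#'
#' @param feature current feature value.
#' @param baseline rest-baseline value.
#' @param variant `"ratio"` or `"difference"`.
#' @param scale multiplier for the difference variant.
#' @return signed percent (ratio) or scaled difference.
#' @export
apsc <- function(feature, baseline, variant = c("ratio", "difference"),
                 scale = 100) {
  variant <- match.arg(variant)
  if (variant == "ratio") {
    if (baseline == 0)
      stop("zero baseline: use variant = \"difference\"", call. = FALSE)
    return(100 * (feature - baseline) / abs(baseline))
  }
  scale * (feature - baseline)
}

#' z-score feedback
#'
#' @param feature current feature value.
#' @param rest_mean,rest_sd calibration rest statistics (`rest_sd > 0`).
#' @return `(feature - rest_mean) / rest_sd`.
#' @export
zscore_feedback <- function(feature, rest_mean, rest_sd) {
  if (!is.finite(rest_sd) || rest_sd <= 0)
    stop("degenerate calibration: rest_sd must be > 0", call. = FALSE)
  (feature - rest_mean) / rest_sd
}

#' Relative change of ROI size
#'
#' Feedback variant for spatial-augmentation protocols: the percent
#' change of the supra-threshold ROI extent against its baseline size.
#'
#' @param current_size,baseline_size voxel counts (`baseline_size > 0`).
#' @return signed percent change.
#' @export
roi_size_change <- function(current_size, baseline_size) {
  if (baseline_size <= 0) stop("baseline ROI size must be > 0",
                               call. = FALSE)
  100 * (current_size - baseline_size) / baseline_size
}

#' Baseline state of one modality
#'
#' @param value initial baseline (typically the mean feature over all
#'   calibration rest intervals).
#' @param modality `"EEG"` or `"FMRI"`.
#' @param policy `"replace"` updates to the last rest block's mean
#'   (tracks slow drift); `"cumulative"` averages all rest blocks seen
#'   so far (the calibration-style estimate).
#' @param n_contributing number of features behind `value`.
#' @return a `baseline_state`.
#' @export
baseline_state <- function(value, modality = c("EEG", "FMRI"),
                           policy = c("replace", "cumulative"),
                           n_contributing = 1L) {
  modality <- match.arg(modality)
  policy <- match.arg(policy)
  stopifnot(n_contributing >= 1L)
  structure(list(value = value, n_contributing = as.integer(n_contributing),
                 history = numeric(), modality = modality, policy = policy),
            class = "baseline_state")
}

#' Update a baseline at the end of a Rest block
#'
#' Called by the protocol engine when leaving a Rest block with that
#' block's features. Empty feature sets leave the state unchanged with
#' a warning.
#'
#' @param state a [baseline_state()].
#' @param rest_block_features feature values collected over the
#'   just-finished Rest block.
#' @return the updated state (`history` gains the block mean).
#' @export
update_baseline <- function(state, rest_block_features) {
  rest_block_features <- rest_block_features[is.finite(rest_block_features)]
  if (!length(rest_block_features)) {
    warning("empty rest block: baseline unchanged")
    return(state)
  }
  block_mean <- mean(rest_block_features)
  state$history <- c(state$history, block_mean)
  state$value <- if (state$policy == "replace") block_mean
                 else mean(state$history)
  state$n_contributing <- length(rest_block_features)
  state
}

#' Combine per-modality feedback into one sample
#'
#' @param eeg_nfb,fmri_nfb normalized per-modality values (either may be
#'   `NULL` for unimodal passthrough, except in bimodal modes, where a
#'   missing modality is an error naming the stalled pipeline).
#' @param mode `"vector2d"` keeps the \[EEG, fMRI\] vector; `"mean"`
#'   averages; `"weighted"` uses `w * eeg + (1 - w) * fmri`.
#' @param w weight on the EEG value for `"weighted"`.
#' @param timestamp seconds from session start.
#' @return an `nfb_sample`: `values`, `modalities`, `timestamp`,
#'   `normalized`.
#' @export
combine_nfb <- function(eeg_nfb = NULL, fmri_nfb = NULL,
                        mode = c("vector2d", "mean", "weighted"), w = 0.5,
                        timestamp = NA_real_) {
  mode <- match.arg(mode)
  if (is.null(eeg_nfb) && is.null(fmri_nfb))
    stop("no feedback value from either pipeline", call. = FALSE)
  if (is.null(eeg_nfb) || is.null(fmri_nfb)) {
    if (mode != "vector2d" && !(mode == "weighted" && (w %in% c(0, 1))))
      stop("bimodal mode '", mode, "' but the ",
           if (is.null(eeg_nfb)) "EEG" else "fMRI",
           " pipeline produced no value", call. = FALSE)
    val <- if (is.null(eeg_nfb)) fmri_nfb else eeg_nfb
    return(structure(list(values = val,
                          modalities = if (is.null(eeg_nfb)) "FMRI" else "EEG",
                          timestamp = timestamp, normalized = NA),
                     class = "nfb_sample"))
  }
  values <- switch(mode,
                   vector2d = c(EEG = eeg_nfb, FMRI = fmri_nfb),
                   mean = (eeg_nfb + fmri_nfb) / 2,
                   weighted = w * eeg_nfb + (1 - w) * fmri_nfb)
  structure(list(values = values, modalities = c("EEG", "FMRI"),
                 timestamp = timestamp, normalized = NA),
            class = "nfb_sample")
}

#' @export
print.nfb_sample <- function(x, ...) {
  cat("<nfb_sample>", paste(sprintf("%.3f", x$values), collapse = " / "),
      "(", paste(x$modalities, collapse = "+"), ") at t =", x$timestamp,
      "s\n")
  invisible(x)
}

#' Normalize a raw feedback value for display
#'
#' Affine map of the raw value onto \[0, 1\] between a floor and the
#' feedback target, clamped at both ends (values beyond the target show
#' as fully achieved; values below the floor as zero rather than
#' negative).
#'
#' @param raw raw feedback value.
#' @param target value mapping to 1 (`target > floor`).
#' @param floor value mapping to 0.
#' @return value in \[0, 1\].
#' @export
normalize_for_display <- function(raw, target, floor = 0) {
  if (target <= floor) stop("target must exceed floor", call. = FALSE)
  pmin(pmax((raw - floor) / (target - floor), 0), 1)
}
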