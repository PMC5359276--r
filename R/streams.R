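#' Multichannel EEG stream
#'
#' The unit flowing through the EEG pipeline: a channels-by-samples
#' matrix in microvolt with its sampling rate, channel labels and
#' time-stamped markers. Marker samples use R's 1-based indexing
#' internally; the BrainVision writer handles the file convention.
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels unique channel names (default Ch1..ChN).
#' @param markers data frame with columns `kind` (one of TTL, R_PEAK,
#'   PROTOCOL, NFB_UPDATE), `sample` (1-based index) and `label`.
#' @return an `eeg_stream` object.
#' @export
eeg_stream <- function(data, fs, channel_labels = NULL, markers = NULL) {
  data <- as.matrix(data)
  if (is.null(channel_labels))
    channel_labels <- paste0("Ch", seq_len(nrow(data)))
  if (is.null(markers))
    markers <- data.frame(kind = character(), sample = integer(),
                          label = character())
  s <- structure(list(data = data, fs = fs,
                      channel_labels = channel_labels, markers = markers),
                 class = "eeg_stream")
  validate_eeg_stream(s)
}

validate_eeg_stream <- function(s) {
  if (!is.numeric(s$fs) || s$fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (anyDuplicated(s$channel_labels))
    stop("channel labels must be unique", call. = FALSE)
  if (length(s$channel_labels) != nrow(s$data))
    stop("one label per channel required", call. = FALSE)
  allowed <- c("TTL", "R_PEAK", "PROTOCOL", "NFB_UPDATE", "NEW_SEGMENT")
  if (nrow(s$markers)) {
    if (!all(s$markers$kind %in% allowed))
      stop("marker kind outside the closed set: ",
           paste(setdiff(unique(s$markers$kind), allowed), collapse = ", "),
           call. = FALSE)
    if (any(s$markers$sample < 1L) || any(s$markers$sample > ncol(s$data)))
      stop("marker sample indices must lie within the stream", call. = FALSE)
  }
  s
}

#' @export
print.eeg_stream <- function(x, ...) {
  cat(sprintf("<eeg_stream> %d ch x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$markers)))
  invisible(x)
}

n_samples <- function(stream) ncol(stream$data)

#' Ordered fMRI volume series
#'
#' @param data 4D numeric array (x, y, z, volume), BOLD in arbitrary
#'   units.
#' @param tr repetition time in seconds.
#' @param timestamps acquisition-completion times in seconds from
#'   session start; defaults to `(1:n) * tr`.
#' @param affine 4x4 voxel-to-world matrix; defaults to 2 x 2 x 4 mm
#'   voxels.
#' @return a `volume_series` object.
#' @export
volume_series <- function(data, tr, timestamps = NULL, affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("volume data must be a 4D array (x, y, z, volume)", call. = FALSE)
  nv <- dim(data)[4]
  if (is.null(timestamps)) timestamps <- seq_len(nv) * tr
  if (length(timestamps) != nv || (nv > 1 && any(diff(timestamps) <= 0)))
    stop("timestamps must be strictly increasing, one per volume",
         call. = FALSE)
  if (is.null(affine)) affine <- diag(c(2, 2, 4, 1))
  structure(list(data = data, tr = tr, timestamps = timestamps,
                 affine = affine),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d grid, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

n_volumes <- function(vs) dim(vs$data)[4]

#' Region-of-interest mask
#'
#' @param voxels integer vector of linear voxel indices into the grid.
#' @param grid_shape the grid the indices refer to.
#' @param label text label.
#' @return a `roi_mask` object.
#' @export
roi_mask <- function(voxels, grid_shape, label = "roi") {
  voxels <- sort(unique(as.integer(voxels)))
  if (length(voxels) && (min(voxels) < 1L || max(voxels) > prod(grid_shape)))
    stop("voxel indices outside the grid", call. = FALSE)
  structure(list(voxels = voxels, grid_shape = as.integer(grid_shape),
                 label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels in %s grid\n", x$label,
              length(x$voxels), paste(x$grid_shape, collapse = "x")))
  invisible(x)
}
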