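#' Detect R peaks on an ECG channel
#'
#' Band-passes the channel to the QRS-dominant 5-15 Hz range, rectifies,
#' and thresholds at a multiple of the rolling median absolute
#' deviation; a refractory period suppresses double detections. Simple
#' and dependency-free, adequate for synthetic and replayed ECG.
#'
#' @param ecg numeric vector (single channel) or an [eeg_stream()] whose
#'   last channel is taken.
#' @param fs sampling rate in Hz (taken from the stream if given one).
#' @param refractory minimum inter-peak gap in seconds.
#' @param k threshold as a multiple of the MAD of the filtered signal.
#' @return integer vector of 1-based R-peak sample indices (empty, with
#'   a warning, for flat input).
#' @export
detect_r_peaks <- function(ecg, fs = NULL, refractory = 0.3, k = 4) {
  if (inherits(ecg, "eeg_stream")) {
    fs <- ecg$fs
    ecg <- ecg$data[nrow(ecg$data), ]
  }
  if (is.null(fs)) stop("fs required for a bare vector", call. = FALSE)
  n <- length(ecg)
  if (n <= refractory * fs) stop("input shorter than the refractory window",
                                 call. = FALSE)
  if (max(ecg) - min(ecg) < .Machine$double.eps * 100) {
    warning("flat-line ECG: no peaks detected")
    return(integer())
  }
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, ecg - mean(ecg))
  # derivative -> squaring -> moving-window integration merges the
  # ringing lobes of one QRS into a single energy hump
  d <- c(0, diff(y))
  sq <- d^2
  wlen <- max(3L, as.integer(round(0.15 * fs)))
  integ <- as.numeric(stats::filter(sq, rep(1 / wlen, wlen), sides = 2))
  integ[is.na(integ)] <- 0
  # adaptive floor (MAD) plus a fraction of the QRS energy envelope, so
  # template-subtraction ghosts well below the true beats are ignored
  thr <- max(k * mad(integ), 0.25 * quantile(integ, 0.999),
             .Machine$double.eps)
  above <- which(integ > thr)
  if (!length(above)) {
    warning("no ECG activity above threshold")
    return(integer())
  }
  gap <- as.integer(round(refractory * fs))
  # anchor refinement: the coarse position is the energy-envelope
  # maximum (unimodal per QRS); the fine anchor is the steep zero
  # crossing between the complex's two dominant opposite lobes. That
  # crossing is sample-accurate and independent of complex polarity,
  # so template epochs stay aligned across beats and across streamed
  # re-detections.
  refine <- function(coarse) {
    w <- as.integer(round(0.08 * fs))
    lo <- max(1L, coarse - w); hi <- min(length(y), coarse + w)
    seg <- y[lo:hi]
    i_max <- lo + which.max(seg) - 1L
    i_min <- lo + which.min(seg) - 1L
    a <- min(i_max, i_min); b <- max(i_max, i_min)
    if (a < b && sign(y[a]) != sign(y[b])) {
      cross <- which(diff(sign(y[a:b])) != 0)
      if (length(cross)) return(a + cross[1] - 1L)
    }
    if (abs(y[i_max]) >= abs(y[i_min])) i_max else i_min
  }
  cand <- integer(); height <- numeric()
  i <- 1L
  while (i <= length(above)) {
    j <- i
    while (j < length(above) && above[j + 1] - above[j] <= gap %/% 3L)
      j <- j + 1L
    run <- above[i]:above[j]
    cand <- c(cand, refine(run[which.max(integ[run])]))
    height <- c(height, max(integ[run]))
    i <- j + 1L
  }
  # greedy by energy: strongest humps first, refractory suppression
  keep <- logical(length(cand))
  for (i in order(height, decreasing = TRUE))
    if (!any(keep & abs(cand - cand[i]) <= gap)) keep[i] <- TRUE
  sort(cand[keep])
}

#' Sliding template buffer for average-artifact subtraction
#'
#' FIFO of equal-length channel-by-sample epochs; the running mean over
#' the stored epochs is the artifact template.
#'
#' @param capacity maximum number of stored epochs (5-15 is typical for
#'   TR-locked gradient artifacts, 10-20 for pulse intervals).
#' @param epoch_length epoch length in samples.
#' @param n_channels channel count.
#' @return a `template_buffer` object.
#' @export
template_buffer <- function(capacity, epoch_length, n_channels) {
  stopifnot(capacity >= 1, epoch_length >= 1, n_channels >= 1)
  structure(list(capacity = as.integer(capacity),
                 epoch_length = as.integer(epoch_length),
                 n_channels = as.integer(n_channels),
                 epochs = list()),
            class = "template_buffer")
}

buffer_push <- function(buf, epoch) {
  stopifnot(nrow(epoch) == buf$n_channels, ncol(epoch) == buf$epoch_length)
  buf$epochs <- c(buf$epochs, list(epoch))
  if (length(buf$epochs) > buf$capacity)
    buf$epochs <- buf$epochs[-1L]
  buf
}

buffer_template <- function(buf) {
  if (!length(buf$epochs)) return(NULL)
  Reduce(`+`, buf$epochs) / length(buf$epochs)
}

#' Sliding-template artifact subtraction (AAS)
#'
#' One operation, two anchor sources: TR-boundary markers for the
#' gradient artifact, R peaks for the ballistocardiogram. Each anchored
#' epoch is corrected by subtracting the mean of the previously stored
#' raw epochs, then pushed into the shifting buffer. The first epoch has
#' no template yet: it passes through unmodified and is flagged; later
#' epochs are corrected with however many epochs are stored, so output
#' is defined from the very first anchor. Samples outside any anchored
#' epoch pass through.
#'
#' @param stream an [eeg_stream()].
#' @param anchors 1-based sample indices of epoch starts (TTL samples or
#'   R peaks). Gradient mode requires equal spacing within `tolerance`.
#' @param buffer a [template_buffer()] or a capacity count (buffer then
#'   built with the inferred epoch length).
#' @param epoch_length epoch length in samples; default the minimum
#'   anchor spacing.
#' @param mode `"gradient"` (strict spacing check) or `"bcg"`.
#' @param tolerance admissible anchor-spacing deviation in samples for
#'   gradient mode; violations raise a desynchronization error.
#' @return list with `stream` (corrected), `buffer` (updated) and
#'   `flagged` (anchor indices corrected without a full template).
#' @export
template_correct <- function(stream, anchors, buffer = 10L,
                             epoch_length = NULL,
                             mode = c("gradient", "bcg"), tolerance = 1L) {
  mode <- match.arg(mode)
  anchors <- as.integer(anchors)
  if (length(anchors) < 1L) return(list(stream = stream, buffer = buffer,
                                        flagged = integer()))
  if (length(anchors) > 1L) {
    sp <- diff(anchors)
    if (mode == "gradient" && (max(sp) - min(sp)) > tolerance)
      stop("desync: anchor spacing varies by more than ", tolerance,
           " samples in gradient mode", call. = FALSE)
  }
  if (is.null(epoch_length))
    epoch_length <- if (length(anchors) > 1L) {
      # gradient epochs tile the TR exactly; pulse intervals jitter, so
      # a robust central spacing avoids a single short outlier shrinking
      # every epoch
      if (mode == "gradient") min(diff(anchors))
      else as.integer(floor(median(diff(anchors))))
    } else n_samples(stream) - anchors[1] + 1L
  nch <- nrow(stream$data)
  if (!inherits(buffer, "template_buffer"))
    buffer <- template_buffer(buffer, epoch_length, nch)
  data <- stream$data
  nsamp <- ncol(data)
  flagged <- integer()
  for (a in anchors) {
    to <- min(a + epoch_length - 1L, nsamp)
    len <- to - a + 1L
    if (len < 1L) next
    raw <- data[, a:to, drop = FALSE]
    tpl <- buffer_template(buffer)
    if (is.null(tpl)) {
      flagged <- c(flagged, a)
    } else {
      if (length(buffer$epochs) < buffer$capacity) flagged <- c(flagged, a)
      data[, a:to] <- raw - tpl[, seq_len(len), drop = FALSE]
    }
    if (len == epoch_length) buffer <- buffer_push(buffer, raw)
  }
  stream$data <- data
  list(stream = stream, buffer = buffer, flagged = flagged)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward Butterworth filtering per channel (zero phase, so
#' features never lag the data they summarize); markers are preserved.
#'
#' @param stream an [eeg_stream()] or numeric matrix/vector.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param fs sampling rate for bare matrices.
#' @param order filter order.
#' @return the same type as the input, filtered.
#' @export
bandpass <- function(stream, low, high, fs = NULL, order = 4) {
  if (inherits(stream, "eeg_stream")) fs <- stream$fs
  if (is.null(fs)) stop("fs required for bare input", call. = FALSE)
  if (!(low > 0 && high > low && high < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  filt1 <- function(x) as.numeric(signal::filtfilt(bf, x))
  if (inherits(stream, "eeg_stream")) {
    stream$data <- t(apply(stream$data, 1, filt1))
    stream
  } else if (is.matrix(stream)) {
    t(apply(stream, 1, filt1))
  } else {
    filt1(stream)
  }
}

#' Segment a stream into overlapping windows
#'
#' @param stream an [eeg_stream()] or channels-by-samples matrix.
#' @param win window length in seconds (`win * fs` must be an integer).
#' @param overlap fractional overlap in `[0, 1)` (0.95 gives a 5% step).
#' @param fs sampling rate for bare matrices.
#' @return list of windows, each a list with `data` (channels x samples)
#'   and `start_s` (window start in seconds from the stream origin);
#'   empty when the stream is shorter than one window.
#' @export
segment_windows <- function(stream, win, overlap = 0, fs = NULL) {
  if (inherits(stream, "eeg_stream")) {
    fs <- stream$fs
    data <- stream$data
  } else {
    data <- if (is.matrix(stream)) stream else matrix(stream, nrow = 1)
  }
  if (is.null(fs)) stop("fs required for bare input", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)",
                                        call. = FALSE)
  L <- win * fs
  if (abs(L - round(L)) > 1e-9) stop("win * fs must be an integer",
                                     call. = FALSE)
  L <- as.integer(round(L))
  step <- L * (1 - overlap)
  if (abs(step - round(step)) > 1e-6) step <- round(step)
  step <- max(as.integer(round(step)), 1L)
  nsamp <- ncol(data)
  if (nsamp < L) return(list())
  starts <- seq.int(1L, nsamp - L + 1L, by = step)
  lapply(starts, function(s0)
    list(data = data[, s0:(s0 + L - 1L), drop = FALSE],
         start_s = (s0 - 1L) / fs))
}
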