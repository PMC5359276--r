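#' Map a normalized feedback sample to display geometry
#'
#' Pure geometry on the unit canvas \[0,1\]^2, no rendering dependency:
#' * `SUN` -- brightness follows the EEG value, radius the fMRI value
#'   (between `r_min` and `r_max`);
#' * `BAR` -- height is the single value, or the mean of the two
#'   normalized values for bimodal input;
#' * `DISK` -- the disk sits at `(x, y) = (EEG, fMRI)`; the goal is the
#'   corner `(1, 1)` where both feedback values are maximal.
#' Unimodal input drives both parameters proportionally.
#'
#' @param nfb an `nfb_sample` whose values are normalized to \[0, 1\]
#'   (anything else is an error), or a bare numeric vector of length 1
#'   or 2 (order \[EEG, fMRI\]).
#' @param metaphor `"SUN"`, `"BAR"` or `"DISK"`.
#' @param tick update index stored in the frame.
#' @param r_min,r_max sun radius range in canvas units.
#' @return a `display_frame`: `metaphor`, `params`, `tick`.
#' @export
map_nfb <- function(nfb, metaphor = c("SUN", "BAR", "DISK"), tick = 0L,
                    r_min = 0.05, r_max = 0.45) {
  metaphor <- match.arg(metaphor)
  values <- if (inherits(nfb, "nfb_sample")) nfb$values else nfb
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("feedback must be normalized to [0, 1] before display",
         call. = FALSE)
  if (length(values) == 1L) values <- c(values, values)  # proportional rule
  eeg <- values[1]; fmri <- values[2]
  params <- switch(metaphor,
                   SUN = list(brightness = eeg,
                              radius = r_min + (r_max - r_min) * fmri),
                   BAR = list(height = mean(values)),
                   DISK = list(x = eeg, y = fmri))
  structure(list(metaphor = metaphor, params = params,
                 tick = as.integer(tick)),
            class = "display_frame")
}

#' @export
print.display_frame <- function(x, ...) {
  cat(sprintf("<display_frame> %s @ tick %d: %s\n", x$metaphor, x$tick,
              paste(names(x$params), sprintf("%.3f", unlist(x$params)),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Export a sequence of display frames as CSV
#'
#' @param frames list of `display_frame`s (one metaphor).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_frames <- function(frames, path) {
  rows <- lapply(frames, function(f)
    cbind(data.frame(tick = f$tick, metaphor = f$metaphor),
          as.data.frame(f$params)))
  write_atomic(function(p)
    utils::write.csv(do.call(rbind, rows), p, row.names = FALSE), path)
  invisible(path)
}
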