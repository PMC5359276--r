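#' Block-design protocol specification
#'
#' Declares the session structure: an optional "Begin" lead-in, then
#' alternating Task/Rest blocks, either with fixed durations or with a
#' flexible task interval that ends once the feedback target is reached.
#' The protocol layer and the feedback-update layer run on the same
#' clock: in fixed mode every block duration must be an exact multiple
#' of `update_period`, so block transitions always coincide with an
#' update tick.
#'
#' @param task_s task-block duration in seconds (fixed mode) or a
#'   length-2 range `c(min, max)` (flexible mode).
#' @param rest_s rest-block duration in seconds.
#' @param n_blocks number of Task/Rest repetitions.
#' @param begin_s duration of the initial Begin period (no task, no
#'   feedback display) in seconds.
#' @param update_period feedback-update period in seconds (0.5 s is a
#'   typical display refresh; EEG-driven protocols often use 0.25 s).
#' @param mode `"fixed"` or `"flexible"`.
#'
#' @return an object of class `protocol_spec` with a normalized `blocks`
#'   data frame (`kind`, `duration`, `min`, `max`).
#' @export
protocol_spec <- function(task_s = 20, rest_s = 20, n_blocks = 4L,
                          begin_s = 10, update_period = 0.5,
                          mode = c("fixed", "flexible")) {
  mode <- match.arg(mode)
  spec <- list(task_s = task_s, rest_s = rest_s,
               n_blocks = as.integer(n_blocks), begin_s = begin_s,
               update_period = update_period, mode = mode)
  class(spec) <- "protocol_spec"
  validate_protocol(spec)
}

#' Validate and normalize a protocol
#'
#' Checks the period-multiplicity constraint: fixed block durations (and
#' the Begin period) must be integer multiples of the update period so
#' that protocol transitions land exactly on feedback-update ticks.
#' Flexible task blocks instead record their admissible range; their end
#' snaps to the first update tick after the target is achieved.
#'
#' @param spec a `protocol_spec` (possibly hand-built).
#' @return the spec with a normalized `blocks` data frame attached.
#' @export
validate_protocol <- function(spec) {
  up <- spec$update_period
  if (!is.numeric(up) || up <= 0) stop("update_period must be > 0",
                                       call. = FALSE)
  if (spec$n_blocks < 0L) stop("n_blocks must be >= 0", call. = FALSE)
  is_mult <- function(d) abs(d / up - round(d / up)) < 1e-9
  if (!is_mult(spec$begin_s))
    stop(sprintf("Begin duration %g s is not a multiple of the update period %g s",
                 spec$begin_s, up), call. = FALSE)
  if (!is_mult(spec$rest_s))
    stop(sprintf("rest duration %g s is not a multiple of the update period %g s",
                 spec$rest_s, up), call. = FALSE)
  if (spec$mode == "fixed") {
    if (length(spec$task_s) != 1L)
      stop("fixed mode takes a single task duration", call. = FALSE)
    if (!is_mult(spec$task_s))
      stop(sprintf("task duration %g s is not a multiple of the update period %g s",
                   spec$task_s, up), call. = FALSE)
    task_row <- data.frame(kind = "TASK", duration = spec$task_s,
                           min = spec$task_s, max = spec$task_s)
  } else {
    if (length(spec$task_s) != 2L || spec$task_s[1] >= spec$task_s[2])
      stop("flexible mode takes task_s = c(min, max) with min < max",
           call. = FALSE)
    task_row <- data.frame(kind = "TASK", duration = NA_real_,
                           min = spec$task_s[1], max = spec$task_s[2])
  }
  blocks <- data.frame(kind = "BEGIN", duration = spec$begin_s,
                       min = spec$begin_s, max = spec$begin_s)
  if (spec$n_blocks > 0L) {
    rest_row <- data.frame(kind = "REST", duration = spec$rest_s,
                           min = spec$rest_s, max = spec$rest_s)
    for (b in seq_len(spec$n_blocks)) blocks <- rbind(blocks, task_row, rest_row)
  }
  rownames(blocks) <- NULL
  spec$blocks <- blocks
  spec
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec>", x$mode, "mode\n")
  cat(sprintf("  Begin %g s, then %d x [Task %s s / Rest %g s], update every %g s\n",
              x$begin_s, x$n_blocks,
              if (x$mode == "fixed") format(x$task_s)
              else paste0("[", x$task_s[1], ",", x$task_s[2], "]"),
              x$rest_s, x$update_period))
  invisible(x)
}

# total fixed-protocol duration in seconds (Begin included); flexible
# protocols use their max task duration
protocol_duration <- function(spec) {
  b <- spec$blocks
  sum(ifelse(is.na(b$duration), b$max, b$duration))
}
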