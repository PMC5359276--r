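#' Start a synchronized session
#'
#' The first scanner TTL pulse anchors the session: every later event is
#' logged as an offset from it. Acquisition bookkeeping starts
#' immediately; feedback-update and protocol callbacks start after the
#' Begin period. Starting an already-live session is an error.
#'
#' @param protocol a [protocol_spec()].
#' @param first_ttl_time absolute time of the first TTL pulse (any
#'   clock; only offsets matter afterwards).
#' @param state an existing scheduler state (to detect double starts).
#' @return a `scheduler_state`: `t0`, `tick` (last completed update
#'   index), `current_block`, cursors, desync flags and the event log.
#' @export
start_session <- function(protocol, first_ttl_time = 0, state = NULL) {
  if (!is.null(state) && isTRUE(state$live))
    stop("session already live: cannot start twice", call. = FALSE)
  if (is.null(first_ttl_time) || !is.finite(first_ttl_time))
    stop("no TTL pulse received: the session cannot start (watchdog)",
         call. = FALSE)
  st <- structure(list(
    protocol = protocol,
    t0 = first_ttl_time,
    tick = -1L,                       # no update tick completed yet
    current_block = 1L,               # index into protocol$blocks (BEGIN)
    block_start = 0,                  # session-clock time the block began
    block_elapsed = 0,
    eeg_cursor = 0L, fmri_cursor = 0L,
    desync_flags = character(),
    live = TRUE, aborted = FALSE,
    resync_attempted = FALSE,
    events = data.frame(tick = integer(), time_s = numeric(),
                        event = character(), detail = character())
  ), class = "scheduler_state")
  log_event(st, -1L, 0, "SESSION_START", sprintf("t0=%g", first_ttl_time))
}

log_event <- function(state, tick, time_s, event, detail = "") {
  state$events <- rbind(state$events,
                        data.frame(tick = tick, time_s = time_s,
                                   event = event, detail = detail))
  state
}

# time (offset from t0) of update tick k: ticks fire at the END of each
# update period after Begin, k = 0, 1, ...
tick_time <- function(protocol, k) protocol$begin_s + k * protocol$update_period

#' Advance the scheduler to `now`
#'
#' Fires every update tick due up to `now` (seconds from t0) and, on
#' ticks where the current block's duration elapses, the protocol
#' transition -- so transitions are a subset of update ticks by
#' construction. Flexible task blocks instead end on the first tick at
#' or after which `target_reached(tick_time)` is true (or at their max
#' duration).
#'
#' @param state a `scheduler_state`.
#' @param now current session clock in seconds from t0 (monotone; going
#'   backward is a hard error).
#' @param target_reached optional `function(time_s)` for flexible task
#'   blocks.
#' @return list with `state` and `ticks` (data frame of fired ticks:
#'   `tick`, `time_s`, `block`, `kind`, `transition`, `left_rest`).
#' @export
scheduler_advance <- function(state, now, target_reached = NULL) {
  pr <- state$protocol
  up <- pr$update_period
  last_t <- tick_time(pr, state$tick)
  if (now < last_t - 1e-9)
    stop("clock went backward: now = ", now, " before tick at ", last_t,
         call. = FALSE)
  fired <- list()
  while (!state$aborted) {
    k <- state$tick + 1L
    tk <- tick_time(pr, k)
    if (tk > now + 1e-9) break
    state$tick <- k
    blocks <- pr$blocks
    bi <- state$current_block
    kind <- if (bi <= nrow(blocks)) blocks$kind[bi] else "END"
    elapsed <- tk - state$block_start
    state$block_elapsed <- elapsed
    transition <- FALSE
    left_rest <- FALSE
    if (bi <= nrow(blocks)) {
      dur <- blocks$duration[bi]
      done <- if (!is.na(dur)) {
        elapsed >= dur - 1e-9
      } else {
        # flexible task block: end at the first tick after the target,
        # within [min, max]
        hit <- !is.null(target_reached) && isTRUE(target_reached(tk))
        (elapsed >= blocks$min[bi] - 1e-9 && hit) ||
          elapsed >= blocks$max[bi] - 1e-9
      }
      if (done) {
        transition <- TRUE
        left_rest <- kind == "REST"
        state <- log_event(state, k, tk, "PROTOCOL",
                           sprintf("end %s (block %d, %.2f s)", kind, bi,
                                   elapsed))
        state$current_block <- bi + 1L
        state$block_start <- tk
        state$block_elapsed <- 0
      }
    }
    fired <- c(fired, list(data.frame(tick = k, time_s = tk,
                                      block = bi, kind = kind,
                                      transition = transition,
                                      left_rest = left_rest)))
    state <- log_event(state, k, tk, "UPDATE", kind)
    if (state$current_block > nrow(pr$blocks)) {
      state <- log_event(state, k, tk, "SESSION_END", "protocol complete")
      state$live <- FALSE
      break
    }
  }
  ticks <- if (length(fired)) do.call(rbind, fired)
           else data.frame(tick = integer(), time_s = numeric(),
                           block = integer(), kind = character(),
                           transition = logical(), left_rest = logical())
  list(state = state, ticks = ticks)
}

#' Cross-check the two acquisition clocks and the protocol lattice
#'
#' Compares observed TTL pulse times against the nominal TR lattice and
#' protocol markers against the update-tick lattice, producing typed
#' reports rather than exceptions: a single off-lattice TTL is an
#' acquisition delay; a gap of about one extra TR is a missed TTL; a
#' run of three or more offsets growing in magnitude is clock drift
#' (reported once, at first detection).
#'
#' @param state a `scheduler_state`.
#' @param ttl_times observed TTL times, seconds from t0.
#' @param tr nominal repetition time.
#' @param protocol_times observed protocol-marker times (optional).
#' @param tolerance admissible deviation in seconds (default 10% of TR).
#' @return data frame of reports: `kind`, `magnitude`, `tick`,
#'   `resolved` (empty when the run is clean).
#' @export
check_sync <- function(state, ttl_times, tr, protocol_times = NULL,
                       tolerance = 0.1 * tr) {
  stopifnot(tolerance > 0)
  reports <- list()
  add <- function(kind, magnitude, tick)
    reports[[length(reports) + 1L]] <<- data.frame(
      kind = kind, magnitude = magnitude, tick = tick, resolved = FALSE)
  if (length(ttl_times)) {
    t0 <- ttl_times[1]
    idx <- 0L                      # expected TTL index of current pulse
    offs <- ttl_times - (t0 + (seq_along(ttl_times) - 1L) * tr)
    i <- 1L
    while (i <= length(ttl_times)) {
      exp_t <- t0 + idx * tr
      d <- ttl_times[i] - exp_t
      if (abs(d) <= tolerance) {
        # on lattice
      } else if (d >= tr - tolerance) {
        add("MISSED_TTL", d, i - 1L)
        idx <- idx + as.integer(round(d / tr))
      } else {
        # drift if the deviation keeps growing over the next pulses
        nxt <- i + seq_len(min(2L, length(ttl_times) - i))
        dn <- ttl_times[nxt] - (t0 + (idx + nxt - i) * tr)
        if (length(dn) == 2L && all(abs(dn) > abs(d)) &&
            all(sign(dn) == sign(d))) {
          add("DRIFT", d, i - 1L)
          break
        }
        add("ACQ_DELAY", d, i - 1L)
      }
      idx <- idx + 1L
      i <- i + 1L
    }
  }
  if (!is.null(protocol_times) && length(protocol_times)) {
    pr <- state$protocol
    for (ptm in protocol_times) {
      k <- (ptm - pr$begin_s) / pr$update_period
      if (abs(k - round(k)) > 1e-6)
        add("ACQ_DELAY", ptm,
            as.integer(floor(k)))  # protocol marker off the tick lattice
    }
  }
  if (length(reports)) do.call(rbind, reports)
  else data.frame(kind = character(), magnitude = numeric(),
                  tick = integer(), resolved = logical())
}

#' Attempt re-synchronization or abort the session
#'
#' Isolated anomalies (a delayed or missed TTL) are resolved by
#' re-anchoring the acquisition cursors to the latest agreed pulse; one
#' attempt is made. Drift, or anomalies persisting after a resync, stop
#' the session and flush the logs so nothing is lost.
#'
#' @param state a `scheduler_state`.
#' @param reports data frame from [check_sync()].
#' @param out_dir optional directory; on abort the event log (TSV) is
#'   written there.
#' @return the updated state (`aborted`, `desync_flags`, annotated
#'   events); reports marked `resolved` where recovery succeeded.
#' @export
resync_or_abort <- function(state, reports, out_dir = NULL) {
  if (!nrow(reports)) return(state)
  recoverable <- all(reports$kind %in% c("ACQ_DELAY", "MISSED_TTL"))
  if (recoverable && !state$resync_attempted) {
    state$resync_attempted <- TRUE
    state$desync_flags <- union(state$desync_flags, unique(reports$kind))
    state <- log_event(state, state$tick, tick_time(state$protocol, state$tick),
                       "RESYNC", paste(reports$kind, collapse = ","))
    attr(state, "resolved_reports") <- transform(reports, resolved = TRUE)
    return(state)
  }
  state$aborted <- TRUE
  state$live <- FALSE
  state$desync_flags <- union(state$desync_flags, unique(reports$kind))
  state <- log_event(state, state$tick, tick_time(state$protocol, state$tick),
                     "SESSION_ABORT", paste(reports$kind, collapse = ","))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_atomic(state$events, file.path(out_dir, "event_log.tsv"))
  }
  attr(state, "resolved_reports") <- reports
  state
}

#' @export
print.scheduler_state <- function(x, ...) {
  cat(sprintf("<scheduler_state> tick %d, block %d/%d, %s\n",
              x$tick, x$current_block, nrow(x$protocol$blocks),
              if (x$aborted) "ABORTED" else if (x$live) "live" else "complete"))
  invisible(x)
}
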