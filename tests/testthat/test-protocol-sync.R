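test_that("protocol validation enforces the period-multiplicity law", {
  expect_silent(protocol_spec(task_s = 20, rest_s = 20,
                              update_period = 0.5))
  expect_error(protocol_spec(task_s = 20, rest_s = 20,
                             update_period = 0.3),
               "not a multiple")
  fl <- protocol_spec(task_s = c(5, 60), rest_s = 20, mode = "flexible",
                      update_period = 0.25)
  expect_equal(fl$blocks$max[fl$blocks$kind == "TASK"][1], 60)
  expect_true(is.na(fl$blocks$duration[fl$blocks$kind == "TASK"][1]))
})

test_that("session start anchors the clock and rejects double starts", {
  pr <- tiny_protocol()
  st <- start_session(pr, first_ttl_time = 12)
  expect_equal(st$t0, 12)
  expect_true(all(st$events$time_s >= 0))
  expect_error(start_session(pr, 0, state = st), "already live")
  expect_error(start_session(pr, first_ttl_time = NULL), "TTL")
  # Begin 10 s, update 0.5 s: first update tick fires at t0 + 10
  adv <- scheduler_advance(st, 10)
  expect_equal(adv$ticks$time_s[1], 10)
  expect_equal(adv$ticks$tick[1], 0)
})

test_that("protocol transitions coincide with update ticks", {
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 2,
                      begin_s = 0, update_period = 0.25)
  st <- start_session(pr, 0)
  adv <- scheduler_advance(st, 100)
  tk <- adv$ticks
  # every tick on the lattice
  expect_true(all(abs(tk$time_s / 0.25 - round(tk$time_s / 0.25)) < 1e-9))
  trans <- tk$tick[tk$transition]
  expect_true(all(trans %in% tk$tick))
  # task/rest boundaries every 80 ticks (tick 0 closes the empty Begin)
  expect_equal(trans, c(0, 80, 160, 240, 320))
  expect_false(adv$state$live)   # protocol complete
})

test_that("flexible blocks snap to the next update tick after the target", {
  pr <- protocol_spec(task_s = c(5, 60), rest_s = 20, n_blocks = 1,
                      begin_s = 0, update_period = 0.25,
                      mode = "flexible")
  st <- start_session(pr, 0)
  adv <- scheduler_advance(st, 100,
                           target_reached = function(tk) tk >= 7.13)
  tk <- adv$ticks
  t_end <- tk$time_s[tk$transition & tk$kind == "TASK"]
  expect_equal(t_end, 7.25)
})

test_that("the scheduler clock must be monotone", {
  pr <- tiny_protocol()
  st <- start_session(pr, 0)
  adv <- scheduler_advance(st, 30)
  expect_error(scheduler_advance(adv$state, 10), "backward")
})

test_that("a clean run produces no sync reports", {
  pr <- tiny_protocol()
  st <- start_session(pr, 0)
  expect_equal(nrow(check_sync(st, (0:40) * 2, tr = 2)), 0L)
})

test_that("an injected TTL delay yields exactly one typed report", {
  pr <- tiny_protocol()
  st <- start_session(pr, 0)
  ttl <- (0:40) * 2
  tol <- 0.1 * 2
  ttl[20] <- ttl[20] + 3 * tol
  rep <- check_sync(st, ttl, tr = 2, tolerance = tol)
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$kind, "ACQ_DELAY")
  expect_equal(rep$tick, 19L)
  expect_equal(rep$magnitude, 3 * tol, tolerance = 1e-9)
})

test_that("clock drift is detected within five simulated minutes", {
  pr <- tiny_protocol()
  st <- start_session(pr, 0)
  n <- 150                       # 5 min of TRs at 2 s
  ttl <- (0:(n - 1)) * 2 * (1 + 0.001)   # 0.1% rate error
  rep <- check_sync(st, ttl, tr = 2)
  expect_true("DRIFT" %in% rep$kind)
  drift_at <- rep$tick[rep$kind == "DRIFT"][1]
  expect_lt(drift_at * 2, 300)
})

test_that("a missed TTL is resynced; persistent drift aborts", {
  pr <- tiny_protocol()
  st <- start_session(pr, 0)
  ttl <- (0:30) * 2
  ttl <- ttl[-15]                # one pulse lost
  rep <- check_sync(st, ttl, tr = 2)
  expect_equal(rep$kind, "MISSED_TTL")
  st2 <- resync_or_abort(st, rep)
  expect_false(st2$aborted)
  expect_true("MISSED_TTL" %in% st2$desync_flags)
  expect_true(attr(st2, "resolved_reports")$resolved)

  out <- file.path(tempdir(), "abort-test")
  drift <- check_sync(st, (0:100) * 2.01, tr = 2)
  st3 <- resync_or_abort(st, drift, out_dir = out)
  expect_true(st3$aborted)
  expect_true(file.exists(file.path(out, "event_log.tsv")))
  expect_true(any(st3$events$event == "SESSION_ABORT"))
})

test_that("closed-loop sessions are deterministic and causal", {
  cal <- shared_calibration()
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 2,
                      begin_s = 10, update_period = 0.5)
  s1 <- run_session(cal, gain = 0.3, seed = 77, protocol = pr)
  s2 <- run_session(cal, gain = 0.3, seed = 77, protocol = pr)
  expect_identical(serialize(s1$events, NULL), serialize(s2$events, NULL))
  expect_identical(serialize(s1$nfb, NULL), serialize(s2$nfb, NULL))

  n <- s1$nfb
  # every feedback sample on the update-tick lattice
  k <- (n$time_s - pr$begin_s) / pr$update_period
  expect_true(all(abs(k - round(k)) < 1e-9))
  # causality: features never use data newer than tick minus latency
  ok <- !is.na(n$eeg_window_end_s)
  expect_true(all(n$eeg_window_end_s[ok] + s1$latency$eeg <=
                    n$time_s[ok] + 1e-9))
  vok <- n$fmri_volume > 0
  expect_true(all(n$fmri_volume[vok] * 2 + s1$latency$fmri <=
                    n$time_s[vok] + 1e-9))
  # clean run: no sync reports, session completes
  expect_equal(nrow(s1$sync_reports), 0L)
  expect_false(s1$scheduler$live)
  expect_false(s1$scheduler$aborted)
})

test_that("baseline updates re-center rest feedback near zero", {
  cal <- shared_calibration()
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 3,
                      begin_s = 10, update_period = 0.5)
  s <- run_session(cal, gain = 0, seed = 5, protocol = pr)
  n <- s$nfb
  # per rest block, the mean raw EEG feedback recomputed against the
  # baseline established from it is zero by construction; here we check
  # the session-level consequence: rest-block feedback stays small
  # relative to the feedback targets
  rest <- n[n$kind == "REST" & !is.na(n$eeg_raw), ]
  last_block <- rest[rest$block == max(rest$block), ]
  expect_lt(abs(mean(last_block$eeg_raw)), cal$eeg_target)
})

test_that("session summary and print methods run", {
  cal <- shared_calibration()
  pr <- protocol_spec(task_s = 20, rest_s = 20, n_blocks = 2,
                      begin_s = 10, update_period = 0.5)
  s <- run_session(cal, gain = 0, seed = 3, protocol = pr)
  expect_output(print(s), "nfb_session")
  sm <- summary(s)
  expect_s3_class(sm, "summary.nfb_session")
  expect_output(print(sm), "task-block means")
  expect_true(is.finite(sm$mean_task_nfb))
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(s); grDevices::dev.off()
  expect_true(file.exists(f))
})
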