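session_fixture <- local({
  p <- protocol_config()
  run_session(p, phase = "operant", duration = 2 * 3600, seed = 17)
})

test_that("JSONL write/read round trip is lossless", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  ev <- session_fixture$events
  write_events(ev, f)
  back <- read_events(f)
  expect_identical(nrow(back), nrow(ev))
  expect_equal(back$t, ev$t)
  expect_identical(back$event_type, ev$event_type)
  expect_identical(back$trial_id, ev$trial_id)
  expect_identical(back$mouse_id, ev$mouse_id)
  expect_equal(back$delay, ev$delay)
  expect_identical(back$outcome, ev$outcome)
  expect_identical(back$is_catch, ev$is_catch)
  # writing the re-read stream reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_events(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("malformed files are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  ev <- session_fixture$events[1:20, ]
  write_events(ev, f)
  lines <- readLines(f)
  lines[5] <- substr(lines[5], 1, 10)  # truncate a record
  writeLines(lines, f)
  expect_error(read_events(f), "line 5")

  # timestamp regression
  ev2 <- ev
  ev2$t[3] <- ev2$t[2]  # fine: ties allowed
  expect_silent(write_events(ev2, f))
  ev2$t[3] <- ev2$t[2] - 1
  expect_error(write_events(ev2, f), "non-decreasing")
  good <- withr::local_tempfile(fileext = ".jsonl")
  write_events(ev, good)
  lines <- readLines(good)
  writeLines(c(lines[1], lines[3], lines[2], lines[-(1:3)]), good)
  expect_error(read_events(good), "regression")

  # missing header
  writeLines(lines[-1], good)
  expect_error(read_events(good), "header|schema")
})

test_that("an empty session (header + SESSION_START) is a valid file", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  ev <- session_fixture$events[session_fixture$events$event_type ==
                                 "SESSION_START", , drop = FALSE]
  write_events(ev, f)
  back <- read_events(f)
  expect_identical(nrow(back), 1L)
  expect_identical(back$event_type, "SESSION_START")
  expect_identical(nrow(events_to_trials(back)), 0L)
})

test_that("events_to_trials reconstructs the engine's own trial table", {
  ev <- session_fixture$events
  tr <- events_to_trials(ev)
  own <- session_fixture$trials
  expect_identical(nrow(tr), nrow(own))
  expect_identical(tr$outcome, own$outcome)
  expect_identical(tr$trial_id, own$trial_id)
  expect_equal(tr$t_start, own$t_start)
  expect_equal(tr$first_lick_latency, own$first_lick_latency)
  expect_identical(tr$n_licks, own$n_licks)
  expect_equal(tr$licks, own$licks)
})

test_that("a log whose payload disagrees with its licks is a consistency error", {
  ev <- session_fixture$events
  # tamper: relabel a MISS as a HIT
  i <- which(ev$event_type == "TRIAL_END" & ev$outcome == "MISS")[1]
  ev$outcome[i] <- "HIT"
  expect_error(events_to_trials(ev), "consistency")
})

test_that("mixed-cage files are grouped per cage", {
  p <- protocol_config()
  s2 <- run_session(p, phase = "operant", duration = 1200, seed = 19,
                    cage_id = 3L)
  ev1 <- session_fixture$events
  mixed <- rbind(ev1, s2$events)
  mixed <- mixed[order(mixed$t), ]
  tr <- events_to_trials(mixed)
  expect_identical(nrow(tr), nrow(session_fixture$trials) + nrow(s2$trials))
  expect_identical(sort(unique(tr$cage_id)), c(0L, 3L))
  expect_identical(tr$outcome[tr$cage_id == 3L], s2$trials$outcome)
})

test_that("CSV trial export agrees with the JSONL-derived table on shared fields", {
  f <- withr::local_tempfile(fileext = ".csv")
  own <- session_fixture$trials
  write_trials(own, f)
  back <- read_trials(f)
  for (col in c("trial_id", "outcome", "is_catch", "rewarded", "n_licks")) {
    expect_identical(back[[col]], own[[col]], label = col)
  }
  expect_equal(back$t_start, own$t_start)
  expect_equal(back$first_lick_latency, own$first_lick_latency)
  expect_equal(back$licks, own$licks, tolerance = 1e-9)
})

test_that("structural validation catches unpaired trials and tones on catch trials", {
  ev <- session_fixture$events
  expect_true(validate_events(ev))
  drop_end <- ev[!(ev$event_type == "TRIAL_END" & ev$trial_id == 1L), ]
  expect_error(validate_events(drop_end), "unpaired")
  bad <- ev
  i_catch <- which(bad$event_type == "TRIAL_START" & bad$is_catch)[1]
  extra <- bad[i_catch, ]
  extra$event_type <- "TONE_ON"
  bad <- rbind(bad, extra)
  bad <- bad[order(bad$t), ]
  expect_error(validate_events(bad), "TONE_ON")
})
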