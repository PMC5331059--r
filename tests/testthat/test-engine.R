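test_that("inter-trial intervals are uniform on the range plus 20 s per time-out", {
  shp <- detection_config("shaping")
  hab <- habituation_config()
  set.seed(1)
  u <- replicate(500, sample_iti(shp, 0L))
  expect_true(all(u >= 5 & u <= 9))
  v <- replicate(200, sample_iti(hab, 0L))
  expect_true(all(v >= 30 & v <= 300))
  w <- replicate(200, sample_iti(shp, 1L))
  expect_true(all(w >= 25 & w <= 29))
  degen <- detection_config("shaping", iti_range = c(7, 7))
  expect_equal(sample_iti(degen, 0L), 7)
  expect_equal(sample_iti(degen, 2L), 47)
})

test_that("quiet-period deferral walks past every offending lick", {
  expect_equal(enforce_quiet_period(102, numeric(0), 5), 102)
  expect_equal(enforce_quiet_period(102, 100, 5), 105)
  expect_equal(enforce_quiet_period(101, c(100, 103, 106), 5), 111)
  # licks already quiet_period old do not defer
  expect_equal(enforce_quiet_period(105, 100, 5), 105)
  expect_error(enforce_quiet_period(101, c(103, 100), 5), "sorted")
  expect_true(is.na(enforce_quiet_period(101, c(100, 103, 106), 5,
                                         horizon = 110)))
})

test_that("trial geometry follows phase and delay", {
  shp <- detection_config("shaping")
  st0 <- engine_state("shaping", 0)
  set.seed(1)
  sp <- build_trial(st0, shp, 1000)
  expect_equal(sp$tone_onset, 1000.5)
  expect_equal(sp$win_open, 0.5)              # window opens at tone onset
  expect_equal(sp$win_close, 3.5)             # 3 s window
  expect_false(sp$is_catch)

  st75 <- engine_state("shaping", 0.75)
  set.seed(1)
  sp75 <- build_trial(st75, shp, 1000)
  expect_equal(sp75$win_open, 1.25)
  expect_equal(sp75$win_close, 4.25)          # [tone + 0.75, tone + 3.75)

  op <- detection_config("operant")
  set.seed(2)
  spo <- build_trial(engine_state("operant", 0.75), op, 0)
  expect_equal(spo$tone_offset - spo$tone_onset, 0.5)
  expect_equal(spo$win_close - spo$win_open, 2)
  # catch probability 1/3
  set.seed(3)
  draws <- replicate(9000, build_trial(engine_state("operant", 0.75), op, 0)$is_catch)
  p_hat <- mean(draws)
  expect_lt(abs(p_hat - 1 / 3), 2.576 * sqrt(1 / 3 * 2 / 3 / 9000))
})

test_that("trial classification implements the go/no-go contingencies", {
  tone <- spec_at(delay = 0.75)   # early [0, 1.25), response [1.25, 3.25)
  ctch <- spec_at(delay = 0.75, is_catch = TRUE)

  hit <- classify_trial(tone, 1.8)
  expect_identical(hit$label, "HIT")
  expect_true(hit$rewarded); expect_false(hit$timeout_applied)
  expect_equal(hit$first_lick_latency, 1.8)

  early <- classify_trial(tone, 0.9)
  expect_identical(early$label, "EARLY")
  expect_false(early$rewarded); expect_true(early$timeout_applied)

  expect_identical(classify_trial(ctch, numeric(0))$label, "CORRECT_REJECTION")
  expect_identical(classify_trial(ctch, 2.0)$label, "FALSE_ALARM")
  expect_identical(classify_trial(ctch, 0.5)$label, "EARLY_CATCH")
  expect_identical(classify_trial(tone, numeric(0))$label, "MISS")

  # an early first lick dominates later in-window licks
  expect_identical(classify_trial(tone, c(0.9, 1.8))$label, "EARLY")
  # drinking licks after the window close never change the outcome
  expect_identical(classify_trial(tone, c(1.8, 3.3, 3.6))$label, "HIT")
  expect_identical(classify_trial(tone, c(3.3, 3.6))$label, "MISS")
  expect_error(classify_trial(tone, c(2.0, 1.0)), "sorted")
})

test_that("delay advances one step when the peak latency tracks the window", {
  sched <- delay_schedule()
  st <- engine_state("shaping", 0.25)
  geom <- list(win_open = 0.75, win_close = 3.75)
  expect_equal(maybe_advance_delay(1.2, geom, st, sched), 0.5)
  expect_equal(maybe_advance_delay(0.5, geom, st, sched), 0.25)  # early peak
  expect_equal(maybe_advance_delay(NA, geom, st, sched), 0.25)
  st_max <- engine_state("shaping", 0.75)
  geom_max <- list(win_open = 1.25, win_close = 4.25)
  expect_equal(maybe_advance_delay(2.0, geom_max, st_max, sched), 0.75)  # cap
})

test_that("a never-licking cage yields only misses and correct rejections", {
  p <- protocol_config(agent = silent_agent())
  s <- run_session(p, phase = "operant", duration = 4 * 3600, seed = 5)
  expect_gt(nrow(s$trials), 100)
  expect_true(all(s$trials$outcome %in% c("MISS", "CORRECT_REJECTION")))
  expect_false(any(s$trials$rewarded))
  expect_identical(sum(s$events$event_type == "LICK"), 0L)
  expect_identical(sum(s$events$event_type == "REWARD_ON"), 0L)
})

test_that("outcome counts partition tone and catch trials on a simulated session", {
  p <- protocol_config()
  s <- run_session(p, phase = "operant", duration = 3 * 3600, seed = 11)
  tr <- s$trials
  n_tone <- sum(!tr$is_catch); n_catch <- sum(tr$is_catch)
  expect_identical(sum(tr$outcome %in% c("HIT", "MISS", "EARLY")), n_tone)
  expect_identical(sum(tr$outcome %in% c("FALSE_ALARM", "CORRECT_REJECTION",
                                         "EARLY_CATCH")), n_catch)
  # tone-trial outcomes never appear on catch trials and vice versa
  expect_false(any(tr$outcome[tr$is_catch] %in% c("HIT", "MISS", "EARLY")))
})

test_that("habituation trials deliver water for the first 10 s and emit no tones", {
  p <- protocol_config()
  s <- run_session(p, phase = "habituation", duration = 1800, seed = 3)
  ev <- s$events
  expect_false(any(ev$event_type %in% c("TONE_ON", "TONE_OFF")))
  on <- ev[ev$event_type == "REWARD_ON", ]
  off <- ev[ev$event_type == "REWARD_OFF", ]
  starts <- ev[ev$event_type == "TRIAL_START", ]
  expect_identical(nrow(on), nrow(starts))
  expect_equal(on$t, starts$t)
  expect_equal(off$t - on$t, rep(10, nrow(on)))
})

test_that("free water reaches ~10% of non-catch shaping trials at zero delay", {
  p <- protocol_config(agent = silent_agent())
  s <- run_session(p, phase = "shaping", duration = Inf, n_trials = 10000,
                   seed = 13, response_delay = 0)
  tone <- s$trials[!s$trials$is_catch, ]
  expect_identical(nrow(tone), 10000L)         # shaping has no catch trials
  p_hat <- mean(tone$free_water)
  expect_lt(abs(p_hat - 0.1), 2.576 * sqrt(0.1 * 0.9 / 10000))
  # free-water trials are rewarded even without licks, and classified normally
  expect_true(all(tone$rewarded == tone$free_water))
  expect_true(all(tone$outcome == "MISS"))
})

test_that("identical seeds give identical sessions; different seeds differ", {
  p <- protocol_config()
  a <- run_session(p, phase = "operant", duration = 1200, seed = 21)
  b <- run_session(p, phase = "operant", duration = 1200, seed = 21)
  expect_identical(a$events, b$events)
  expect_identical(a$trials, b$trials)
  c <- run_session(p, phase = "operant", duration = 1200, seed = 22)
  expect_false(identical(a$events, c$events))
})

test_that("training program advances delays monotonically to the maximum and switches phase", {
  p <- protocol_config(cages = cage_schedule(n_cages = 2))
  prog <- run_training_program(p, n_days = 8, seed = 2)
  d <- prog$daily
  for (cg in unique(d$cage_id)) {
    dd <- d[d$cage_id == cg, ]
    dd <- dd[order(dd$day_index), ]
    expect_true(all(diff(dd$delay) >= 0))
    expect_true(all(dd$delay <= 0.75))
    # operant phase only after the delay schedule is complete
    op_days <- dd$day_index[dd$phase == "operant"]
    if (length(op_days)) {
      expect_true(all(dd$delay[dd$day_index %in% op_days] == 0.75))
      first_op <- min(op_days)
      expect_true(all(dd$phase[dd$day_index > first_op] == "operant"))
    }
  }
  # catch trials appear only in the operant phase
  tr <- prog$trials
  expect_false(any(tr$is_catch[tr$phase == "shaping"]))
  expect_gt(sum(tr$is_catch[tr$phase == "operant"]), 0)
  # free water disappears once the delay leaves zero
  expect_false(any(tr$free_water[tr$delay > 0]))
})
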