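# Discrete-event trial engine: trial construction, quiet-period gating, lick
# classification, reward/punishment contingencies, delay advancement, and
# session orchestration for one cage of virtual mice.
#
# Randomness: one RNG per session, seeded by the caller (run_session /
# run_training_program seed it via split_seed()). Draw order is fixed and
# documented: at block start, per mouse in id order, the sleep timeline then
# the spontaneous lick stream; then per trial, (1) the ITI uniform, (2) the
# catch Bernoulli, (3) the free-water Bernoulli, (4) per mouse in id order
# the impulsivity draw (plus lick-time uniform), (5) per mouse in id order
# the detection draw (plus latency), (6) drinking-bout draws. Identical
# seeds therefore give byte-identical logs.

#' Sample the next inter-trial interval
#'
#' Uniform on the configured range, plus one `timeout_duration` (default
#' 20 s) for every pending time-out accrued from early responses since the
#' last trial. Time-outs accumulate additively.
#'
#' @param config a [detection_config()] or [habituation_config()].
#' @param pending_timeouts number of unserved time-outs.
#' @return The interval in seconds; draws one uniform variate from the
#'   session RNG.
#' @export
sample_iti <- function(config, pending_timeouts = 0L) {
  stopifnot(pending_timeouts >= 0)
  u <- stats::runif(1, config$iti_range[1], config$iti_range[2])
  timeout <- if (!is.null(config$timeout_duration)) config$timeout_duration else 20
  u + timeout * pending_timeouts
}

#' Defer a trial onset until the quiet period is satisfied
#'
#' Returns the earliest `t >= candidate_onset` such that no lick falls in
#' `[t - quiet_period, t)`. Enforcement is by deferral: the onset slides
#' forward past each offending lick rather than resampling the interval.
#' Deterministic given the lick stream.
#'
#' @param candidate_onset proposed trial start, seconds.
#' @param lick_times sorted ascending lick times (unsorted input errors).
#' @param quiet_period required lick-free seconds before onset.
#' @param horizon latest admissible onset; if deferral passes it the
#'   function returns `NA` (a "deferred" marker -- the caller re-evaluates
#'   once the lick stream has grown or the session window moves on).
#' @return Onset time in seconds, or `NA_real_` if deferred past `horizon`.
#' @export
enforce_quiet_period <- function(candidate_onset, lick_times, quiet_period,
                                 horizon = Inf) {
  if (is.unsorted(lick_times)) {
    stop("lick_times must be sorted ascending", call. = FALSE)
  }
  t <- candidate_onset
  if (length(lick_times)) {
    relevant <- lick_times[lick_times >= candidate_onset - quiet_period]
    for (L in relevant) {
      if (L < t) t <- L + quiet_period else break
      if (t > horizon) return(NA_real_)
    }
  }
  if (t > horizon) NA_real_ else t
}

#' Construct the next trial's specification
#'
#' Window geometry follows the engine's current response delay: the tone
#' starts `pre_stim_silence` after trial start; the response window opens
#' `response_delay` after tone onset and lasts `response_window_duration`.
#' The early window is `[t_start, window open)` -- it includes the
#' pre-stimulus silence and, at positive delays, the tone itself. Catch
#' status is Bernoulli(`catch_fraction`); free water is
#' Bernoulli(`free_water_fraction`) on non-catch trials only. Catch trials
#' keep identical window geometry (their tone onset is virtual).
#'
#' @param state an engine state (see [engine_state()]).
#' @param config a [detection_config()].
#' @param t_start trial start on the session clock, seconds.
#' @return A `trial_spec` list with absolute `t_start`, `tone_onset` and
#'   window offsets `win_open`/`win_close` relative to `t_start`.
#' @export
build_trial <- function(state, config, t_start) {
  geom <- window_geometry(config, state$current_delay)
  is_catch <- config$catch_fraction > 0 && stats::runif(1) < config$catch_fraction
  free_water <- !is_catch && config$free_water_fraction > 0 &&
    stats::runif(1) < config$free_water_fraction
  structure(list(trial_id = state$trial_counter + 1L,
                 t_start = t_start,
                 is_catch = is_catch,
                 delay = state$current_delay,
                 tone_onset = t_start + geom$tone_on,
                 tone_offset = t_start + geom$tone_off,
                 win_open = geom$win_open,
                 win_close = geom$win_close,
                 free_water = free_water),
            class = "trial_spec")
}

#' Classify one trial from its lick times
#'
#' Outcomes follow go/no-go convention with an early window. The first lick
#' decides: a first lick inside the early window `[0, win_open)` makes the
#' trial `EARLY` (tone trial) or `EARLY_CATCH` (catch trial) and schedules a
#' time-out; otherwise at least one lick inside the response window
#' `[win_open, win_close)` makes it `HIT` (tone, rewarded) or `FALSE_ALARM`
#' (catch); no lick in either window is `MISS` or `CORRECT_REJECTION`.
#' Licks after the response window (e.g. drinking during reward delivery)
#' never change the outcome. `first_lick_latency` is the first lick time
#' minus trial start whenever any lick occurred.
#'
#' @param spec a `trial_spec` from [build_trial()].
#' @param lick_times sorted ascending absolute lick times within the trial.
#' @return A `trial_outcome` list: `label`, `first_lick_latency`,
#'   `rewarded`, `timeout_applied`.
#' @export
classify_trial <- function(spec, lick_times) {
  if (is.unsorted(lick_times)) {
    stop("lick_times must be sorted ascending", call. = FALSE)
  }
  rel <- lick_times - spec$t_start
  first <- if (length(rel)) rel[1] else NA_real_
  early <- length(rel) && rel[1] >= 0 && rel[1] < spec$win_open
  in_window <- any(rel >= spec$win_open & rel < spec$win_close)
  if (early) {
    label <- if (spec$is_catch) "EARLY_CATCH" else "EARLY"
  } else if (in_window) {
    label <- if (spec$is_catch) "FALSE_ALARM" else "HIT"
  } else {
    label <- if (spec$is_catch) "CORRECT_REJECTION" else "MISS"
  }
  list(label = label,
       first_lick_latency = first,
       rewarded = label == "HIT" || isTRUE(spec$free_water),
       timeout_applied = label %in% c("EARLY", "EARLY_CATCH"))
}

#' Engine state for one cage
#'
#' @param phase `"habituation"`, `"shaping"` or `"operant"`.
#' @param current_delay current required response delay, seconds; must be a
#'   step of the delay schedule.
#' @param schedule a [delay_schedule()].
#' @return A list of class `engine_state`.
#' @export
engine_state <- function(phase = "shaping", current_delay = 0,
                         schedule = delay_schedule()) {
  check_that(current_delay %in% schedule$steps, "current_delay",
             "a step of the delay schedule")
  structure(list(phase = phase,
                 current_delay = current_delay,
                 pending_timeouts = 0L,
                 last_lick_time = -Inf,
                 trial_counter = 0L),
            class = "engine_state")
}

#' Advance the required response delay when performance justifies it
#'
#' The delay increases one schedule step when the day's peak first-lick
#' latency has shifted along with (i.e. falls inside) the current response
#' window; otherwise it is unchanged. It never exceeds the schedule maximum.
#'
#' @param daily_peak_latency the day's modal first-lick latency, seconds
#'   from trial start (`NA` if no licks -- no advancement).
#' @param geometry window offsets for the current delay, as returned by
#'   `window_geometry()` or a `trial_spec` (`win_open`, `win_close`).
#' @param state an [engine_state()].
#' @param schedule a [delay_schedule()].
#' @return The new delay in seconds.
#' @export
maybe_advance_delay <- function(daily_peak_latency, geometry, state, schedule) {
  cur <- state$current_delay
  if (is.na(daily_peak_latency)) return(cur)
  inside <- daily_peak_latency >= geometry$win_open &&
    daily_peak_latency < geometry$win_close
  if (!inside) return(cur)
  i <- match(cur, schedule$steps)
  if (is.na(i) || i >= length(schedule$steps)) return(cur)
  schedule$steps[i + 1L]
}

# ---------------------------------------------------------------------------
# collectors: preallocated growing columns for events and trial records

new_collector <- function(template, n0 = 1024L) {
  env <- new.env(parent = emptyenv())
  env$n <- 0L
  env$cap <- n0
  env$cols <- lapply(template, function(proto) rep(proto, n0))
  env$list_cols <- list()
  env
}

collector_push <- function(env, rows) {
  k <- max(lengths(rows[!vapply(rows, is.list, TRUE)]), 1L)
  while (env$n + k > env$cap) {
    env$cols <- lapply(env$cols, function(col) c(col, col))
    for (nm in names(env$list_cols)) {
      length(env$list_cols[[nm]]) <- 2L * env$cap
    }
    env$cap <- 2L * env$cap
  }
  idx <- (env$n + 1L):(env$n + k)
  for (nm in names(rows)) {
    v <- rows[[nm]]
    if (is.list(v)) {
      if (is.null(env$list_cols[[nm]])) env$list_cols[[nm]] <- vector("list", env$cap)
      env$list_cols[[nm]][idx] <- v
    } else {
      env$cols[[nm]][idx] <- v
    }
  }
  env$n <- env$n + k
  invisible(env)
}

collector_df <- function(env) {
  out <- lapply(env$cols, function(col) col[seq_len(env$n)])
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  for (nm in names(env$list_cols)) {
    df[[nm]] <- env$list_cols[[nm]][seq_len(env$n)]
  }
  df
}

event_template <- function() {
  list(t = NA_real_, cage_id = NA_integer_, mouse_id = NA_integer_,
       event_type = NA_character_, trial_id = NA_integer_,
       day_index = NA_integer_, phase = NA_character_,
       is_catch = NA, delay = NA_real_, win_open = NA_real_,
       win_close = NA_real_, free_water = NA,
       outcome = NA_character_, rewarded = NA, timeout_applied = NA,
       first_lick_latency = NA_real_)
}

trial_template <- function() {
  list(trial_id = NA_integer_, cage_id = NA_integer_, day_index = NA_integer_,
       phase = NA_character_, t_start = NA_real_, is_catch = NA,
       delay = NA_real_, win_open = NA_real_, win_close = NA_real_,
       free_water = NA, outcome = NA_character_, rewarded = NA,
       timeout_applied = NA, first_lick_latency = NA_real_,
       n_licks = NA_integer_)
}

# ---------------------------------------------------------------------------
# block runners

# Simulate detection trials (shaping or operant) for one cage over [t0, t1).
# `agents` carry their day's wake timelines. Mutates nothing; returns the
# updated engine state and last trial-end time.
run_detection_block <- function(t0, t1, config, agents, cages, state,
                                ev, tr, cage_id, day_index, phase,
                                keep_events = TRUE, max_trials = Inf,
                                round_ms = TRUE) {
  # per-mouse spontaneous streams for the block, merged (draw order: mouse id)
  sp_t <- numeric(0); sp_m <- integer(0)
  for (a in agents) {
    licks <- spontaneous_licks(a, t0, t1, cages)
    sp_t <- c(sp_t, licks)
    sp_m <- c(sp_m, rep(a$mouse_id, length(licks)))
  }
  o <- order(sp_t)
  sp_t <- if (round_ms) round(sp_t[o], 3) else sp_t[o]
  sp_m <- sp_m[o]
  sp_in_trial <- logical(length(sp_t))

  # dynamically appended licks (impulsive, evoked, drinking), kept sorted
  ex_t <- numeric(0)
  geom <- window_geometry(config, state$current_delay)
  span_max <- geom$win_close + config$reward_duration + 0.1
  quiet <- config$quiet_period
  rnd <- function(x) if (round_ms) round(x, 3) else x

  t_prev_end <- t0
  n_done <- 0L
  repeat {
    if (n_done >= max_trials) break
    iti <- sample_iti(config, state$pending_timeouts)
    state$pending_timeouts <- 0L
    cand <- t_prev_end + iti
    # licks that can defer the onset: past extras plus the full spont stream
    lo <- cand - quiet
    near <- sort(c(ex_t[ex_t >= lo],
                   sp_t[sp_t >= lo & sp_t < t1]))
    onset <- enforce_quiet_period(cand, near, quiet, horizon = t1 - span_max)
    if (is.na(onset) || onset + span_max > t1) break
    onset <- rnd(onset)

    spec <- build_trial(state, config, onset)
    state$trial_counter <- spec$trial_id

    # assemble this trial's licks
    t_close <- onset + spec$win_close
    sel <- sp_t >= onset & sp_t < t_close
    lick_t <- sp_t[sel]; lick_m <- sp_m[sel]
    gen_t <- numeric(0)
    for (a in agents) {
      il <- impulsive_lick(a, spec)
      if (length(il)) {
        il <- rnd(il)
        lick_t <- c(lick_t, il); lick_m <- c(lick_m, a$mouse_id)
        gen_t <- c(gen_t, il)
      }
    }
    if (!spec$is_catch) {
      for (a in agents) {
        tl <- tone_response(a, spec)
        if (length(tl)) {
          tl <- rnd(tl)
          lick_t <- c(lick_t, tl); lick_m <- c(lick_m, a$mouse_id)
          gen_t <- c(gen_t, tl)
        }
      }
    }
    o2 <- order(lick_t)
    lick_t <- lick_t[o2]; lick_m <- lick_m[o2]

    out <- classify_trial(spec, lick_t)

    # contingencies: reward water on a hit (valve opens at the first
    # response-window lick), free water at window close on flagged trials
    reward_on <- NA_real_; reward_off <- NA_real_
    drink_t <- numeric(0); drink_m <- integer(0)
    if (out$label == "HIT") {
      rel <- lick_t - onset
      i_hit <- which(rel >= spec$win_open & rel < spec$win_close)[1]
      reward_on <- lick_t[i_hit]
      reward_off <- reward_on + config$reward_duration
      dm <- lick_m[i_hit]
      drinker <- agents[[match(dm, vapply(agents, `[[`, 0L, "mouse_id"))]]
      drink_t <- rnd(drinking_licks(drinker, reward_on, reward_off))
      drink_m <- rep(dm, length(drink_t))
    } else if (spec$free_water) {
      reward_on <- t_close
      reward_off <- reward_on + config$free_water_duration
      awake <- vapply(agents, function(a) awake_at(a$wake, reward_on), TRUE)
      if (any(awake)) {
        drinker <- agents[[which(awake)[1]]]
        drink_t <- rnd(drinking_licks(drinker, reward_on, reward_off))
        drink_m <- rep(drinker$mouse_id, length(drink_t))
      }
    }
    if (out$timeout_applied) state$pending_timeouts <- state$pending_timeouts + 1L

    t_end <- rnd(max(t_close, if (is.na(reward_off)) -Inf else reward_off))
    # spontaneous licks during reward delivery belong to the trial span too
    sel2 <- sp_t >= t_close & sp_t < t_end
    all_t <- c(lick_t, sp_t[sel2], drink_t)
    all_m <- c(lick_m, sp_m[sel2], drink_m)
    sp_in_trial <- sp_in_trial | sel | sel2
    if (length(all_t)) {
      o3 <- order(all_t)
      all_t <- all_t[o3]; all_m <- all_m[o3]
    }
    # extras = engine-generated licks (impulsive, evoked, drinking); the
    # spontaneous stream stays in sp_t. Trials never overlap, so appending
    # this trial's sorted extras keeps ex_t sorted.
    gen_t <- c(gen_t, drink_t)
    if (length(gen_t)) ex_t <- c(ex_t, sort(gen_t))

    # record
    collector_push(tr, list(
      trial_id = spec$trial_id, cage_id = cage_id, day_index = day_index,
      phase = phase, t_start = onset, is_catch = spec$is_catch,
      delay = spec$delay, win_open = spec$win_open, win_close = spec$win_close,
      free_water = spec$free_water, outcome = out$label,
      rewarded = out$rewarded, timeout_applied = out$timeout_applied,
      first_lick_latency = if (length(all_t)) rnd(all_t[1] - onset) else NA_real_,
      n_licks = length(all_t),
      licks = list(rnd(all_t - onset)),
      lick_mice = list(all_m)))

    if (keep_events) {
      push_trial_events(ev, spec, out, all_t, all_m, reward_on, reward_off,
                        t_end, cage_id, day_index, phase, config)
    }
    t_prev_end <- t_end
    n_done <- n_done + 1L
  }
  # inter-trial licks are logged too (the spout is recorded continuously);
  # they carry no trial_id
  if (keep_events && any(!sp_in_trial)) {
    idx <- which(!sp_in_trial)
    collector_push(ev, list(t = sp_t[idx], cage_id = rep(cage_id, length(idx)),
                            mouse_id = sp_m[idx],
                            event_type = rep("LICK", length(idx))))
  }
  state
}

push_trial_events <- function(ev, spec, out, lick_t, lick_m, reward_on,
                              reward_off, t_end, cage_id, day_index, phase,
                              config) {
  id <- spec$trial_id
  collector_push(ev, list(
    t = spec$t_start, cage_id = cage_id, event_type = "TRIAL_START",
    trial_id = id, day_index = day_index, phase = phase,
    is_catch = spec$is_catch, delay = spec$delay,
    win_open = spec$win_open, win_close = spec$win_close,
    free_water = spec$free_water))
  if (!spec$is_catch) {
    collector_push(ev, list(t = spec$tone_onset, cage_id = cage_id,
                            event_type = "TONE_ON", trial_id = id))
    collector_push(ev, list(t = spec$tone_offset, cage_id = cage_id,
                            event_type = "TONE_OFF", trial_id = id))
  }
  if (length(lick_t)) {
    collector_push(ev, list(t = lick_t, cage_id = rep(cage_id, length(lick_t)),
                            mouse_id = lick_m,
                            event_type = rep("LICK", length(lick_t)),
                            trial_id = rep(id, length(lick_t))))
  }
  if (!is.na(reward_on)) {
    collector_push(ev, list(t = reward_on, cage_id = cage_id,
                            event_type = "REWARD_ON", trial_id = id))
    collector_push(ev, list(t = reward_off, cage_id = cage_id,
                            event_type = "REWARD_OFF", trial_id = id))
  }
  if (out$timeout_applied) {
    collector_push(ev, list(t = spec$t_start + spec$win_close, cage_id = cage_id,
                            event_type = "TIMEOUT_START", trial_id = id,
                            delay = config$timeout_duration))
  }
  collector_push(ev, list(
    t = t_end, cage_id = cage_id, event_type = "TRIAL_END", trial_id = id,
    outcome = out$label, rewarded = out$rewarded,
    timeout_applied = out$timeout_applied,
    first_lick_latency = out$first_lick_latency))
}

# Habituation block: water flows for the first water_on_duration seconds of
# each trial_duration-second trial; no stimulus events are emitted.
run_habituation_block <- function(t0, t1, config, agents, cages, state,
                                  ev, tr, cage_id, day_index,
                                  keep_events = TRUE, max_trials = Inf) {
  sp_t <- numeric(0); sp_m <- integer(0)
  for (a in agents) {
    licks <- spontaneous_licks(a, t0, t1, cages)
    sp_t <- c(sp_t, licks); sp_m <- c(sp_m, rep(a$mouse_id, length(licks)))
  }
  o <- order(sp_t); sp_t <- round(sp_t[o], 3); sp_m <- sp_m[o]
  sp_in_trial <- logical(length(sp_t))
  t_prev_end <- t0
  n_done <- 0L
  repeat {
    if (n_done >= max_trials) break
    iti <- sample_iti(config, 0L)
    onset <- round(t_prev_end + iti, 3)
    if (onset + config$trial_duration > t1) break
    water_off <- onset + config$water_on_duration
    sel <- sp_t >= onset & sp_t < onset + config$trial_duration
    sp_in_trial <- sp_in_trial | sel
    lick_t <- sp_t[sel]
    lick_m <- sp_m[sel]
    for (a in agents) {
      dl <- round(drinking_licks(a, onset, water_off), 3)
      if (length(dl)) { lick_t <- c(lick_t, dl); lick_m <- c(lick_m, rep(a$mouse_id, length(dl))) }
    }
    o2 <- order(lick_t); lick_t <- lick_t[o2]; lick_m <- lick_m[o2]
    state$trial_counter <- state$trial_counter + 1L
    id <- state$trial_counter
    collector_push(tr, list(
      trial_id = id, cage_id = cage_id, day_index = day_index,
      phase = "habituation", t_start = onset, is_catch = FALSE,
      delay = NA_real_, win_open = NA_real_, win_close = NA_real_,
      free_water = TRUE, outcome = NA_character_,
      rewarded = length(lick_t) > 0, timeout_applied = FALSE,
      first_lick_latency = if (length(lick_t)) round(lick_t[1] - onset, 3) else NA_real_,
      n_licks = length(lick_t),
      licks = list(round(lick_t - onset, 3)),
      lick_mice = list(lick_m)))
    if (keep_events) {
      collector_push(ev, list(t = onset, cage_id = cage_id,
                              event_type = "TRIAL_START", trial_id = id,
                              day_index = day_index, phase = "habituation",
                              free_water = TRUE))
      collector_push(ev, list(t = onset, cage_id = cage_id,
                              event_type = "REWARD_ON", trial_id = id))
      if (length(lick_t)) {
        collector_push(ev, list(t = lick_t, cage_id = rep(cage_id, length(lick_t)),
                                mouse_id = lick_m,
                                event_type = rep("LICK", length(lick_t)),
                                trial_id = rep(id, length(lick_t))))
      }
      collector_push(ev, list(t = water_off, cage_id = cage_id,
                              event_type = "REWARD_OFF", trial_id = id))
      collector_push(ev, list(t = onset + config$trial_duration,
                              cage_id = cage_id, event_type = "TRIAL_END",
                              trial_id = id,
                              first_lick_latency = if (length(lick_t)) round(lick_t[1] - onset, 3) else NA_real_))
    }
    t_prev_end <- onset + config$trial_duration
    n_done <- n_done + 1L
  }
  if (keep_events && any(!sp_in_trial)) {
    idx <- which(!sp_in_trial)
    collector_push(ev, list(t = sp_t[idx], cage_id = rep(cage_id, length(idx)),
                            mouse_id = sp_m[idx],
                            event_type = rep("LICK", length(idx))))
  }
  state
}

# ---------------------------------------------------------------------------

#' Run one cage's session
#'
#' Executes a single continuous session (no cage rotation) of the selected
#' phase for one cage of agents, on the session clock starting at `t0`. The
#' session ends when `duration` seconds elapse or `n_trials` trials have
#' completed, whichever comes first. Use [run_training_program()] for
#' multi-day, multi-cage runs on the rotation schedule.
#'
#' @param protocol a [protocol_config()].
#' @param phase phase to run; defaults to the protocol's `phase`.
#' @param duration active session seconds.
#' @param n_trials optional trial-count cap.
#' @param seed integer seed for the session RNG.
#' @param cage_id cage identifier written to all records.
#' @param day_index training day (drives agent learning state; day 1 means
#'   naive agents at learning day 0).
#' @param t0 session-clock origin, seconds since schedule epoch (affects the
#'   dark phase seen by the agents).
#' @param agents optional list of [agent_state()] objects; by default
#'   `protocol$n_mice_per_cage` agents are built from `protocol$agent`.
#' @param response_delay optional delay override (a schedule step).
#' @param keep_events collect the full event stream (default `TRUE`).
#' @return A list of class `gonogo_session`: `events` (data frame),
#'   `trials` (trial-record data frame), `state` (final engine state),
#'   `seed`, `phase`.
#' @export
run_session <- function(protocol, phase = NULL, duration = 3600,
                        n_trials = Inf, seed = 1L, cage_id = 0L,
                        day_index = 1L, t0 = 0, agents = NULL,
                        response_delay = NULL, keep_events = TRUE) {
  stopifnot(inherits(protocol, "gonogo_protocol"))
  phase <- phase %||% protocol$phase
  set.seed(as.integer(seed))
  if (is.null(agents)) {
    agents <- lapply(seq_len(protocol$n_mice_per_cage), function(i) {
      agent_state(protocol$agent, mouse_id = i, day_index = day_index - 1)
    })
  }
  state <- engine_state(phase = phase,
                        current_delay = response_delay %||%
                          (if (phase == "operant") protocol$delays$max_delay else 0),
                        schedule = protocol$delays)
  if (phase == "habituation") state$current_delay <- 0
  ev <- new_collector(event_template(), 4096L)
  tr <- new_collector(trial_template(), 1024L)
  if (keep_events) {
    collector_push(ev, list(t = t0, cage_id = cage_id,
                            event_type = "SESSION_START",
                            day_index = day_index, phase = phase))
  }
  # one sleep/wake timeline per cage, shared by its mice: cage-mates sleep
  # synchronously, which is what shared-nest home cages show
  wake <- sleep_timeline(agents[[1]]$params, t0, t0 + duration, protocol$cages)
  agents <- lapply(agents, function(a) { a$wake <- wake; a })
  if (phase == "habituation") {
    state <- run_habituation_block(t0, t0 + duration, protocol$habituation,
                                   agents, protocol$cages, state, ev, tr,
                                   cage_id, day_index,
                                   keep_events = keep_events,
                                   max_trials = n_trials)
  } else {
    cfg <- protocol[[phase]]
    cfg$response_delay <- state$current_delay
    state <- run_detection_block(t0, t0 + duration, cfg, agents,
                                 protocol$cages, state, ev, tr, cage_id,
                                 day_index, phase,
                                 keep_events = keep_events,
                                 max_trials = n_trials)
  }
  events <- if (keep_events) {
    df <- collector_df(ev)
    df <- df[order(df$t, method = "radix"), , drop = FALSE]  # stable: ties keep push order
    rownames(df) <- NULL
    df
  } else NULL
  structure(list(events = events, trials = collector_df(tr),
                 state = state, seed = as.integer(seed), phase = phase),
            class = "gonogo_session")
}

#' Run the full multi-day, multi-cage training program
#'
#' Simulates the complete paradigm on the rotation schedule: every cage
#' trains in its daily active blocks (6 h/day with the defaults); each cage
#' starts in the shaping phase at zero delay, with 10% free-water trials.
#' At the end of each day the cage's peak first-lick latency is computed
#' and the response delay advanced per [maybe_advance_delay()]; as soon as
#' the delay leaves zero the free-water trials are removed, and the day
#' after a cage completes the delay schedule it moves to the operant phase
#' (short tone, 2 s window, 1/3 silent catch trials). Agents advance their
#' learning state daily.
#'
#' Seeding: each (cage, day) session gets its own seed from
#' [split_seed()], so runs are reproducible and cages independent.
#'
#' @param protocol a [protocol_config()].
#' @param n_days days to simulate.
#' @param seed master seed.
#' @param out_dir if non-`NULL`, write one JSONL event file per cage per day
#'   into this directory (and keep nothing in memory).
#' @param keep_events keep event streams in memory (heavy; default `FALSE`).
#' @param progress print a line per simulated day.
#' @return A list of class `gonogo_program`: `trials` (all cages and days),
#'   `daily` (per cage-day delay/phase table), `events` (list or `NULL`),
#'   `protocol`, `seed`.
#' @export
run_training_program <- function(protocol, n_days = 15L, seed = 1L,
                                 out_dir = NULL, keep_events = FALSE,
                                 progress = FALSE) {
  stopifnot(inherits(protocol, "gonogo_protocol"))
  cages <- protocol$cages
  n_cages <- cages$n_cages
  sched <- protocol$delays
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  cage_delay <- rep(sched$steps[1], n_cages)
  cage_phase <- rep("shaping", n_cages)
  cage_reached_max <- rep(FALSE, n_cages)
  cage_agents <- lapply(seq_len(n_cages), function(ci) {
    lapply(seq_len(protocol$n_mice_per_cage), function(i) {
      agent_state(protocol$agent, mouse_id = i, day_index = 0)
    })
  })
  trial_dfs <- list()
  event_list <- if (keep_events) list() else NULL
  daily <- list()

  for (day in seq_len(n_days)) {
    for (ci in seq_len(n_cages)) {
      cage_index <- ci - 1L
      phase_switched <- cage_reached_max[ci] && cage_phase[ci] == "shaping"
      if (phase_switched) cage_phase[ci] <- "operant"
      phase <- cage_phase[ci]
      cfg <- protocol[[phase]]
      cfg$response_delay <- cage_delay[ci]
      if (cage_delay[ci] > 0) cfg$free_water_fraction <- 0

      set.seed(split_seed(seed, cage_index, day))
      agents <- lapply(cage_agents[[ci]], update_learning, day_index = day - 1)
      state <- engine_state(phase = phase, current_delay = cage_delay[ci],
                            schedule = sched)
      ev <- new_collector(event_template(), 4096L)
      tr <- new_collector(trial_template(), 2048L)
      want_events <- keep_events || !is.null(out_dir)
      blocks <- active_blocks(cages, cage_index, (day - 1) * 86400, day * 86400)
      if (want_events) {
        collector_push(ev, list(t = (day - 1) * 86400, cage_id = cage_index,
                                event_type = "SESSION_START",
                                day_index = day, phase = phase,
                                delay = cage_delay[ci]))
        if (phase_switched) {
          collector_push(ev, list(t = (day - 1) * 86400, cage_id = cage_index,
                                  event_type = "PHASE_CHANGE",
                                  day_index = day, phase = phase))
        }
      }
      for (b in seq_len(nrow(blocks))) {
        t0 <- blocks[b, 1]; t1 <- blocks[b, 2]
        wake <- sleep_timeline(agents[[1]]$params, t0, t1, cages)
        agents <- lapply(agents, function(a) { a$wake <- wake; a })
        if (want_events) {
          collector_push(ev, list(t = t0, cage_id = cage_index,
                                  event_type = "CAGE_ACTIVE", day_index = day))
        }
        state <- run_detection_block(t0, t1, cfg, agents, cages, state,
                                     ev, tr, cage_index, day, phase,
                                     keep_events = want_events)
        if (want_events) {
          collector_push(ev, list(t = t1, cage_id = cage_index,
                                  event_type = "CAGE_INACTIVE", day_index = day))
        }
      }
      cage_agents[[ci]] <- agents
      day_trials <- collector_df(tr)
      trial_dfs[[length(trial_dfs) + 1L]] <- day_trials

      # end-of-day delay advancement from the day's latency distribution
      fl <- first_lick_stats(day_trials)
      geom <- window_geometry(cfg, cage_delay[ci])
      new_delay <- maybe_advance_delay(fl$peak, geom, state, sched)
      daily[[length(daily) + 1L]] <- data.frame(
        day_index = day, cage_id = cage_index, phase = phase,
        delay = cage_delay[ci], n_trials = nrow(day_trials),
        peak_latency = fl$peak, advanced = new_delay > cage_delay[ci],
        stringsAsFactors = FALSE)
      if (new_delay >= sched$max_delay &&
          (new_delay > cage_delay[ci] || cage_delay[ci] >= sched$max_delay)) {
        cage_reached_max[ci] <- TRUE
      }
      cage_delay[ci] <- new_delay

      if (want_events) {
        events <- collector_df(ev)
        events <- events[order(events$t, method = "radix"), , drop = FALSE]
        rownames(events) <- NULL
        if (!is.null(out_dir)) {
          f <- file.path(out_dir, sprintf("events_cage%d_day%02d.jsonl",
                                          cage_index, day))
          write_events(events, f)
        }
        if (keep_events) {
          event_list[[sprintf("cage%d_day%02d", cage_index, day)]] <- events
        }
      }
    }
    if (progress) {
      message(sprintf("day %2d: delays = %s", day,
                      paste(format(cage_delay), collapse = " ")))
    }
  }
  all_trials <- do.call(rbind, trial_dfs)
  rownames(all_trials) <- NULL
  structure(list(trials = all_trials,
                 daily = do.call(rbind, daily),
                 events = event_list,
                 protocol = protocol, seed = as.integer(seed)),
            class = "gonogo_program")
}
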