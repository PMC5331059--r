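# Virtual mouse: a parametric generative model of licking behavior. It is an
# explicitly synthetic agent -- no claim is made of fitting any real animal;
# its job is to produce lick streams with the qualitative structure of real
# home-cage data (spontaneous licking, circadian sleep/wake alternation,
# tone detection with latency, impulsive early licking, multi-day learning)
# so that the engine and the statistics suite can be exercised end to end.
#
# All stochastic methods draw from R's global RNG; callers seed it once per
# session (see run_session() for the documented draw order).

#' Virtual-mouse behavioral parameters
#'
#' The agent is built from four interacting processes:
#'
#' * **Spontaneous licking**: an inhomogeneous Poisson process with intensity
#'   `baseline_lick_rate` while awake (times `dark_activity_gain` in the dark
#'   phase, zero while asleep). This is the idle spout-investigation rate,
#'   not drinking.
#' * **Sleep/wake alternation**: a renewal process of exponential bouts.
#'   `sleep_bout_rate` is the hazard (per awake second, light phase) of
#'   falling asleep -- mean wake bout `1/sleep_bout_rate`, lengthened by
#'   `dark_activity_gain` in the dark; `sleep_bout_duration` is the mean
#'   sleep bout in seconds. A sleeping mouse emits no licks and ignores
#'   tones.
#' * **Tone detection**: on a tone trial an awake mouse responds with
#'   probability `p_detect * exp(-delay_suppression * response_delay)`;
#'   the response is a single lick at the response-window opening plus a
#'   log-normal offset (`latency_median` seconds, `latency_spread` sdlog),
#'   truncated to the window. The exponential factor models the cost of the
#'   enforced wait: longer required delays depress response rates.
#' * **Impulsive licking**: with per-trial probability `impulsivity` an awake
#'   mouse emits one lick uniformly inside the early window.
#'
#' Detection and impulsivity evolve across training days by exponential
#' approach: `p_detect(day) = final + (initial - final) * exp(-day / learning_tau)`
#' and analogously (decreasing) for impulsivity; see [update_learning()].
#' When rewarded (or during habituation water-on periods) the mouse drinks,
#' licking as a Poisson bout at `reward_lick_rate` licks/s; drinking licks
#' are recorded but never change a trial's outcome.
#'
#' Defaults place a default cohort (3 mice per cage, 6 h daily training) in
#' the regime typical of ad libitum group training: per-tone-trial hit rates
#' of a few percent (most trials pass while the mice sleep), false alarms
#' well under 1%, hits roughly three times as frequent as early responses,
#' and a final d-prime near 1.
#'
#' @param baseline_lick_rate spontaneous licks/s while awake (light phase).
#' @param dark_activity_gain multiplier on lick intensity and wake-bout
#'   length during the 12 h dark phase.
#' @param sleep_bout_rate hazard of falling asleep, per awake second.
#' @param sleep_bout_duration mean sleep bout, seconds.
#' @param p_detect_initial,p_detect_final per-trial tone-detection
#'   probabilities at the start and asymptote of learning.
#' @param learning_tau learning time constant, days.
#' @param latency_median median of the log-normal first-lick latency offset
#'   from the response-window opening, seconds.
#' @param latency_spread sdlog of that log-normal (dimensionless).
#' @param impulsivity_initial,impulsivity_final per-trial probability of an
#'   early-window lick at start and asymptote.
#' @param delay_suppression per-second multiplicative cost of the required
#'   response delay on detection probability.
#' @param reward_lick_rate drinking lick rate, licks/s.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(baseline_lick_rate = 0.002,
                         dark_activity_gain = 2,
                         sleep_bout_rate = 1 / 1500,
                         sleep_bout_duration = 2400,
                         p_detect_initial = 0.07,
                         p_detect_final = 0.07,
                         learning_tau = 3,
                         latency_median = 0.35,
                         latency_spread = 0.45,
                         impulsivity_initial = 0.04,
                         impulsivity_final = 0.012,
                         delay_suppression = 0.5,
                         reward_lick_rate = 6) {
  check_scalar_number(baseline_lick_rate, "baseline_lick_rate", lower = 0)
  check_scalar_number(dark_activity_gain, "dark_activity_gain", lower = 0)
  check_scalar_number(sleep_bout_rate, "sleep_bout_rate", lower = 0)
  check_scalar_number(sleep_bout_duration, "sleep_bout_duration", lower = 0)
  check_scalar_number(p_detect_initial, "p_detect_initial", 0, 1)
  check_scalar_number(p_detect_final, "p_detect_final", 0, 1)
  check_that(learning_tau > 0, "learning_tau", "> 0")
  check_scalar_number(latency_median, "latency_median", lower = 0)
  check_scalar_number(latency_spread, "latency_spread", lower = 0)
  check_scalar_number(impulsivity_initial, "impulsivity_initial", 0, 1)
  check_scalar_number(impulsivity_final, "impulsivity_final", 0, 1)
  check_scalar_number(delay_suppression, "delay_suppression", lower = 0)
  check_scalar_number(reward_lick_rate, "reward_lick_rate", lower = 0)
  structure(list(baseline_lick_rate = baseline_lick_rate,
                 dark_activity_gain = dark_activity_gain,
                 sleep_bout_rate = sleep_bout_rate,
                 sleep_bout_duration = sleep_bout_duration,
                 p_detect_initial = p_detect_initial,
                 p_detect_final = p_detect_final,
                 learning_tau = learning_tau,
                 latency_median = latency_median,
                 latency_spread = latency_spread,
                 impulsivity_initial = impulsivity_initial,
                 impulsivity_final = impulsivity_final,
                 delay_suppression = delay_suppression,
                 reward_lick_rate = reward_lick_rate),
            class = "agent_params")
}

#' Instantiate an agent's evolving state
#'
#' @param params an [agent_params()] set.
#' @param mouse_id integer identity retained in logs (the simulator tracks
#'   individuals even though shared-spout hardware cannot).
#' @param day_index training day (0 = naive).
#' @return A list of class `agent_state` with the day's effective
#'   `p_detect` and `impulsivity`.
#' @export
agent_state <- function(params, mouse_id = 1L, day_index = 0) {
  stopifnot(inherits(params, "agent_params"))
  st <- structure(list(params = params,
                       mouse_id = as.integer(mouse_id),
                       day_index = day_index,
                       p_detect = NA_real_,
                       impulsivity = NA_real_,
                       wake = NULL),
                  class = "agent_state")
  update_learning(st, day_index)
}

#' Advance an agent's learning state to a training day
#'
#' Exponential approach between the initial and asymptotic values:
#' `p_detect(day) = final + (initial - final) * exp(-day / tau)`, and the
#' same form (decreasing) for impulsivity. Day 0 returns the initial values.
#'
#' @param state an [agent_state()].
#' @param day_index training day; must not precede the state's current day.
#' @return The updated `agent_state`.
#' @export
update_learning <- function(state, day_index) {
  stopifnot(inherits(state, "agent_state"))
  if (day_index < state$day_index && !is.na(state$p_detect)) {
    stop("day_index must be non-decreasing", call. = FALSE)
  }
  p <- state$params
  decay <- exp(-day_index / p$learning_tau)
  state$day_index <- day_index
  state$p_detect <- p$p_detect_final + (p$p_detect_initial - p$p_detect_final) * decay
  state$impulsivity <- p$impulsivity_final +
    (p$impulsivity_initial - p$impulsivity_final) * decay
  state
}

#' Simulate a sleep/wake timeline
#'
#' Alternating exponential wake and sleep bouts over `[t0, t1)`. The wake
#' hazard is evaluated at bout onset: mean wake `1/sleep_bout_rate`
#' (times `dark_activity_gain` in the dark), mean sleep
#' `sleep_bout_duration`. A `sleep_bout_rate` of 0 means the mouse never
#' sleeps. The initial state is drawn from the stationary wake probability.
#'
#' @param params an [agent_params()] set.
#' @param t0,t1 interval, seconds since schedule epoch.
#' @param schedule a [cage_schedule()] (supplies the dark phase).
#' @return A two-column matrix of wake intervals `(start, end)`.
#' @export
sleep_timeline <- function(params, t0, t1, schedule) {
  stopifnot(t1 > t0)
  if (params$sleep_bout_rate <= 0 || params$sleep_bout_duration <= 0) {
    return(cbind(t0, t1))
  }
  mean_wake_light <- 1 / params$sleep_bout_rate
  p_wake <- mean_wake_light / (mean_wake_light + params$sleep_bout_duration)
  awake <- stats::runif(1) < p_wake
  t <- t0
  starts <- numeric(0); ends <- numeric(0)
  while (t < t1) {
    if (awake) {
      gain <- if (is_dark(schedule, t)) params$dark_activity_gain else 1
      len <- stats::rexp(1, rate = 1 / (mean_wake_light * gain))
      starts <- c(starts, t); ends <- c(ends, min(t + len, t1))
    } else {
      len <- stats::rexp(1, rate = 1 / params$sleep_bout_duration)
    }
    t <- t + len
    awake <- !awake
  }
  cbind(starts, ends)
}

# Vectorized: is the mouse awake at each time, given its wake-interval
# matrix? NULL means "always awake"; a zero-row matrix means asleep
# throughout the span.
awake_at <- function(wake, t) {
  if (is.null(wake)) return(rep(TRUE, length(t)))
  if (nrow(wake) == 0L) return(rep(FALSE, length(t)))
  i <- findInterval(t, wake[, 1])
  i > 0 & t < wake[pmax(i, 1L), 2]
}

#' Spontaneous lick times over an interval
#'
#' Inhomogeneous Poisson process by thinning: intensity
#' `baseline_lick_rate`, multiplied by `dark_activity_gain` in the dark and
#' by zero while asleep.
#'
#' @param state an [agent_state()] whose `wake` field holds the mouse's
#'   wake-interval matrix for the span (from [sleep_timeline()]; `NULL`
#'   means always awake).
#' @param t0,t1 interval, seconds.
#' @param schedule a [cage_schedule()].
#' @return Sorted lick times strictly inside `(t0, t1)`.
#' @export
spontaneous_licks <- function(state, t0, t1, schedule) {
  stopifnot(inherits(state, "agent_state"), t1 >= t0)
  p <- state$params
  rate_max <- p$baseline_lick_rate * max(1, p$dark_activity_gain)
  if (rate_max <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate_max * (t1 - t0))
  if (n == 0L) return(numeric(0))
  tt <- sort(stats::runif(n, t0, t1))
  gain <- ifelse(is_dark(schedule, tt), p$dark_activity_gain, 1)
  keep <- awake_at(state$wake, tt) &
    stats::runif(n) < (p$baseline_lick_rate * gain) / rate_max
  tt[keep]
}

#' Tone-evoked response of one mouse on one tone trial
#'
#' With probability `p_detect * exp(-delay_suppression * delay)` (zero if
#' asleep at tone onset) the mouse emits one lick at the response-window
#' opening plus a log-normal offset, truncated into the window.
#'
#' @param state an [agent_state()].
#' @param spec a trial spec from [build_trial()]; must be a tone trial.
#' @return A single absolute lick time, or `numeric(0)` for no response.
#' @export
tone_response <- function(state, spec) {
  stopifnot(inherits(state, "agent_state"))
  if (isTRUE(spec$is_catch)) {
    stop("tone_response() called on a catch trial", call. = FALSE)
  }
  p <- state$params
  if (!awake_at(state$wake, spec$tone_onset)) return(numeric(0))
  p_resp <- state$p_detect * exp(-p$delay_suppression * spec$delay)
  if (stats::runif(1) >= p_resp) return(numeric(0))
  offset <- stats::rlnorm(1, meanlog = log(p$latency_median),
                          sdlog = p$latency_spread)
  win_len <- spec$win_close - spec$win_open
  offset <- min(offset, win_len - 1e-3)
  spec$t_start + spec$win_open + offset
}

#' Impulsive early-window lick of one mouse on one trial
#'
#' With per-trial probability `impulsivity` (zero if asleep at trial start)
#' the mouse emits one lick uniformly inside the early window.
#'
#' @inheritParams tone_response
#' @return A single absolute lick time, or `numeric(0)`.
#' @export
impulsive_lick <- function(state, spec) {
  stopifnot(inherits(state, "agent_state"))
  if (!awake_at(state$wake, spec$t_start)) return(numeric(0))
  if (stats::runif(1) >= state$impulsivity) return(numeric(0))
  stats::runif(1, 0, spec$win_open) + spec$t_start
}

#' Drinking-bout lick times while water is available
#'
#' Poisson bout at `reward_lick_rate` over `[t_on, t_off)`, emitted only if
#' the mouse is awake at `t_on`.
#'
#' @param state an [agent_state()].
#' @param t_on,t_off water availability interval, seconds.
#' @return Sorted lick times.
#' @export
drinking_licks <- function(state, t_on, t_off) {
  p <- state$params
  if (t_off <= t_on || p$reward_lick_rate <= 0) return(numeric(0))
  if (!awake_at(state$wake, t_on)) return(numeric(0))
  n <- stats::rpois(1, p$reward_lick_rate * (t_off - t_on))
  if (n == 0L) return(numeric(0))
  sort(stats::runif(n, t_on, t_off))
}
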