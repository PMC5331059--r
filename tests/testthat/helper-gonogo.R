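# Shared fixtures and independent oracles for the test suite.

# Independent inverse-normal-CDF oracle: bisection on pnorm. Never calls
# qnorm, so it can certify compute_dprime().
z_bisect <- function(p, iters = 80L) {
  lo <- rep(-10, length(p))
  hi <- rep(10, length(p))
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    below <- stats::pnorm(mid) < p
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

dprime_oracle <- function(h, f) z_bisect(h) - z_bisect(f)

# An agent that never licks at all.
silent_agent <- function() {
  agent_params(baseline_lick_rate = 0, sleep_bout_rate = 0,
               p_detect_initial = 0, p_detect_final = 0,
               impulsivity_initial = 0, impulsivity_final = 0,
               reward_lick_rate = 0)
}

# A non-learning, never-sleeping agent with exact response parameters, used
# for parameter-recovery checks.
fixed_agent <- function(p_detect, impulsivity = 0, baseline = 0) {
  agent_params(baseline_lick_rate = baseline, sleep_bout_rate = 0,
               p_detect_initial = p_detect, p_detect_final = p_detect,
               impulsivity_initial = impulsivity,
               impulsivity_final = impulsivity,
               delay_suppression = 0, reward_lick_rate = 0)
}

# Hand-built trial table for the statistics layer.
make_trials <- function(outcomes, is_catch, latencies = NULL, licks = NULL,
                        day_index = 1L, cage_id = 0L, delay = 0.75,
                        win_open = 1.25, win_close = 3.25) {
  n <- length(outcomes)
  df <- data.frame(trial_id = seq_len(n), cage_id = cage_id,
                   day_index = day_index, phase = "operant",
                   t_start = seq_len(n) * 20, is_catch = is_catch,
                   delay = delay, win_open = win_open, win_close = win_close,
                   free_water = FALSE, outcome = outcomes,
                   rewarded = outcomes == "HIT",
                   timeout_applied = outcomes %in% c("EARLY", "EARLY_CATCH"),
                   first_lick_latency = if (is.null(latencies)) NA_real_ else latencies,
                   n_licks = 0L, stringsAsFactors = FALSE)
  df$licks <- if (is.null(licks)) rep(list(numeric(0)), n) else licks
  df$n_licks <- lengths(df$licks)
  df
}

# A bare operant trial spec at a chosen delay, for classify_trial tests.
spec_at <- function(delay = 0.75, is_catch = FALSE, t_start = 0,
                    phase = c("operant", "shaping")) {
  phase <- match.arg(phase)
  cfg <- detection_config(phase, response_delay = delay)
  st <- engine_state(phase, current_delay = delay)
  # deterministic spec (no catch/free-water draws)
  structure(list(trial_id = 1L, t_start = t_start, is_catch = is_catch,
                 delay = delay,
                 tone_onset = t_start + cfg$pre_stim_silence,
                 tone_offset = t_start + cfg$pre_stim_silence + cfg$tone_duration,
                 win_open = cfg$pre_stim_silence + delay,
                 win_close = cfg$pre_stim_silence + delay +
                   cfg$response_window_duration,
                 free_water = FALSE),
            class = "trial_spec")
}
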