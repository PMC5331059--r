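# Protocol configuration: typed, validated parameter sets for the three
# training phases (waterspout habituation, behavioral shaping, operant task),
# with the published paradigm's values as defaults.

#' Waterspout habituation parameters
#'
#' Habituation makes water available in a trial-wise paradigm with no
#' stimulus: on each trial water flows continuously from the spout for the
#' first `water_on_duration` seconds, inter-trial intervals are drawn
#' uniformly from `iti_range`, and trials run in alternating on/off blocks
#' (default 90 min on, 90 min off) around the clock.
#'
#' @param trial_duration trial length, seconds.
#' @param water_on_duration seconds of free water flow at trial start; must
#'   not exceed `trial_duration`.
#' @param iti_range `(min, max)` seconds for the uniform inter-trial interval.
#' @param on_block,off_block minutes of the alternating trials-on/trials-off
#'   cycle.
#' @return A validated list of class `habituation_config`.
#' @export
habituation_config <- function(trial_duration = 20,
                               water_on_duration = 10,
                               iti_range = c(30, 300),
                               on_block = 90,
                               off_block = 90) {
  check_scalar_number(trial_duration, "trial_duration", lower = 0)
  check_scalar_number(water_on_duration, "water_on_duration", lower = 0)
  check_that(water_on_duration <= trial_duration, "water_on_duration",
             "water_on_duration <= trial_duration")
  check_range(iti_range, "iti_range")
  check_that(iti_range[1] > 0, "iti_range", "min > 0")
  check_scalar_number(on_block, "on_block", lower = 0)
  check_scalar_number(off_block, "off_block", lower = 0)
  check_that(on_block > 0 && off_block > 0, "on_block/off_block", "blocks > 0")
  structure(list(trial_duration = trial_duration,
                 water_on_duration = water_on_duration,
                 iti_range = as.numeric(iti_range),
                 on_block = on_block,
                 off_block = off_block),
            class = "habituation_config")
}

#' Detection-phase parameters (shaping or operant)
#'
#' One tone-detection trial is a `pre_stim_silence` silent lead-in, a tone of
#' `tone_duration` seconds (`tone_freq` Hz at `tone_level` dB SPL -- metadata
#' labels only, no audio is synthesized), and a response window of
#' `response_window_duration` seconds opening `response_delay` seconds after
#' tone onset. Licks before the window opens are "early" responses punished
#' with a `timeout_duration` addition to the next inter-trial interval; a
#' lick inside the window triggers `reward_duration` seconds of water. Trials
#' may only start after a `quiet_period` with no licks. During shaping a
#' `free_water_fraction` of tone trials deliver `free_water_duration` seconds
#' of water at window close regardless of behavior; in the operant phase a
#' `catch_fraction` of trials are silent catch trials used to estimate false
#' alarms.
#'
#' Phase defaults follow the standard paradigm: shaping uses a 1 s tone, a
#' 3 s response window, 10% free-water trials and no catch trials; the
#' operant task shortens the tone to 0.5 s and the window to 2 s, removes
#' free water and interleaves catch trials on 1/3 of trials.
#'
#' @param phase `"shaping"` or `"operant"`; selects the default set.
#' @param pre_stim_silence,tone_duration,response_window_duration,response_delay
#'   trial timing, seconds.
#' @param tone_freq,tone_level stimulus labels (Hz, dB SPL).
#' @param iti_range `(min, max)` seconds, uniform inter-trial interval.
#' @param quiet_period required lick-free seconds before a trial may start.
#' @param reward_duration,free_water_duration,timeout_duration seconds.
#' @param free_water_fraction,catch_fraction probabilities.
#' @return A validated list of class `detection_config`.
#' @export
detection_config <- function(phase = c("shaping", "operant"),
                             pre_stim_silence = 0.5,
                             tone_duration = NULL,
                             tone_freq = 6000,
                             tone_level = 60,
                             response_window_duration = NULL,
                             response_delay = 0,
                             iti_range = c(5, 9),
                             quiet_period = 5,
                             reward_duration = 2,
                             free_water_fraction = NULL,
                             free_water_duration = 0.5,
                             timeout_duration = 20,
                             catch_fraction = NULL) {
  phase <- match.arg(phase)
  if (is.null(tone_duration)) {
    tone_duration <- if (phase == "shaping") 1.0 else 0.5
  }
  if (is.null(response_window_duration)) {
    response_window_duration <- if (phase == "shaping") 3.0 else 2.0
  }
  if (is.null(free_water_fraction)) {
    free_water_fraction <- if (phase == "shaping") 0.1 else 0
  }
  if (is.null(catch_fraction)) {
    catch_fraction <- if (phase == "operant") 1 / 3 else 0
  }
  for (f in c("pre_stim_silence", "tone_duration", "response_window_duration",
              "quiet_period", "reward_duration", "free_water_duration",
              "timeout_duration")) {
    check_scalar_number(get(f), f, lower = 0)
  }
  check_scalar_number(response_delay, "response_delay", lower = 0)
  check_range(iti_range, "iti_range")
  check_scalar_number(free_water_fraction, "free_water_fraction", 0, 1)
  check_that(is.numeric(catch_fraction) && length(catch_fraction) == 1L &&
               catch_fraction >= 0 && catch_fraction < 1,
             "catch_fraction", "0 <= catch_fraction < 1")
  structure(list(phase = phase,
                 pre_stim_silence = pre_stim_silence,
                 tone_duration = tone_duration,
                 tone_freq = tone_freq,
                 tone_level = tone_level,
                 response_window_duration = response_window_duration,
                 response_delay = response_delay,
                 iti_range = as.numeric(iti_range),
                 quiet_period = quiet_period,
                 reward_duration = reward_duration,
                 free_water_fraction = free_water_fraction,
                 free_water_duration = free_water_duration,
                 timeout_duration = timeout_duration,
                 catch_fraction = catch_fraction),
            class = "detection_config")
}

#' Progressive response-delay schedule
#'
#' During shaping the response window is progressively delayed relative to
#' tone onset, in the listed steps, up to a maximum delay. The delay is
#' advanced one step whenever the daily peak first-lick latency has shifted
#' into the current response window (see [maybe_advance_delay()]).
#'
#' @param steps strictly increasing delays in seconds; the final element is
#'   the maximum delay.
#' @return A list of class `delay_schedule` with `steps` and `max_delay`.
#' @export
delay_schedule <- function(steps = c(0, 0.25, 0.5, 0.75)) {
  check_that(is.numeric(steps) && length(steps) >= 1L && all(is.finite(steps)),
             "steps", "non-empty numeric vector")
  check_that(all(diff(steps) > 0) || length(steps) == 1L, "steps",
             "strictly increasing")
  check_that(all(steps >= 0), "steps", "delays >= 0")
  structure(list(steps = as.numeric(steps), max_delay = steps[length(steps)]),
            class = "delay_schedule")
}

#' Full protocol configuration
#'
#' Bundles everything a training run needs: the active phase, parameter sets
#' for all three phases, the delay schedule, the cage rotation schedule and
#' the virtual-mouse agent parameters. `phase` selects which phase
#' [run_session()] executes; [run_training_program()] manages the
#' shaping-to-operant transition itself.
#'
#' @param phase `"habituation"`, `"shaping"` or `"operant"`.
#' @param habituation a [habituation_config()].
#' @param shaping,operant [detection_config()] objects for the two
#'   detection phases.
#' @param delays a [delay_schedule()].
#' @param cages a [cage_schedule()].
#' @param agent an [agent_params()] set shared by all simulated mice.
#' @param n_mice_per_cage mice sharing each waterspout (default 3).
#' @return A list of class `gonogo_protocol`.
#' @export
protocol_config <- function(phase = c("shaping", "operant", "habituation"),
                            habituation = habituation_config(),
                            shaping = detection_config("shaping"),
                            operant = detection_config("operant"),
                            delays = delay_schedule(),
                            cages = cage_schedule(),
                            agent = agent_params(),
                            n_mice_per_cage = 3L) {
  phase <- match.arg(phase)
  stopifnot(inherits(habituation, "habituation_config"),
            inherits(shaping, "detection_config"),
            inherits(operant, "detection_config"),
            inherits(delays, "delay_schedule"),
            inherits(cages, "cage_schedule"),
            inherits(agent, "agent_params"))
  check_scalar_number(n_mice_per_cage, "n_mice_per_cage", lower = 1)
  structure(list(version = protocol_schema_version(),
                 phase = phase,
                 habituation = habituation,
                 shaping = shaping,
                 operant = operant,
                 delays = delays,
                 cages = cages,
                 agent = agent,
                 n_mice_per_cage = as.integer(n_mice_per_cage)),
            class = "gonogo_protocol")
}

#' @rdname protocol_config
#' @export
protocol_schema_version <- function() "gonogo-protocol/1"

#' Read a protocol configuration file
#'
#' The on-disk dialect is a YAML hierarchy mirroring [protocol_config()]:
#' top-level keys `phase`, `n_mice_per_cage` and sections `habituation`,
#' `shaping`, `operant`, `delays`, `cages`, `agent`, each holding the fields
#' of the corresponding constructor. Any field left out takes the default
#' paradigm value, so an empty file yields the default protocol. A `version`
#' key records the dialect version. A commented example ships in
#' `system.file("extdata", "default_protocol.yaml", package = "gonogo")`.
#'
#' @param path path to a YAML protocol file.
#' @return A validated [protocol_config()] object.
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("protocol file does not parse to a key hierarchy: ",
                          path, call. = FALSE)
  if (!is.null(raw$version) && !identical(raw$version, protocol_schema_version())) {
    stop("unsupported protocol version: ", raw$version, call. = FALSE)
  }
  build <- function(ctor, section, ...) {
    args <- raw[[section]] %||% list()
    if ("iti_range" %in% names(args)) args$iti_range <- unlist(args$iti_range)
    if ("steps" %in% names(args)) args$steps <- unlist(args$steps)
    if ("cage_offsets" %in% names(args)) args$cage_offsets <- unlist(args$cage_offsets)
    if ("dark_cycle" %in% names(args)) args$dark_cycle <- unlist(args$dark_cycle)
    do.call(ctor, c(args, list(...)))
  }
  shaping_args <- raw$shaping %||% list()
  operant_args <- raw$operant %||% list()
  shaping_args$phase <- NULL
  operant_args$phase <- NULL
  protocol_config(
    phase = raw$phase %||% "shaping",
    habituation = build(habituation_config, "habituation"),
    shaping = do.call(detection_config,
                      c(list(phase = "shaping"),
                        lapply(shaping_args, function(x) if (length(x) > 1 || is.list(x)) unlist(x) else x))),
    operant = do.call(detection_config,
                      c(list(phase = "operant"),
                        lapply(operant_args, function(x) if (length(x) > 1 || is.list(x)) unlist(x) else x))),
    delays = build(delay_schedule, "delays"),
    cages = build(cage_schedule, "cages"),
    agent = build(agent_params, "agent"),
    n_mice_per_cage = raw$n_mice_per_cage %||% 3L
  )
}

#' Write a protocol configuration file
#'
#' Serializes a protocol to the YAML dialect read by [load_protocol()];
#' `load_protocol(write_protocol(cfg, path))` reproduces an equal object.
#'
#' @param config a [protocol_config()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(config, path) {
  stopifnot(inherits(config, "gonogo_protocol"))
  strip <- function(x) {
    x <- unclass(x)
    x[["max_delay"]] <- NULL  # derived from steps
    x[["period"]] <- NULL     # derived from the block lengths
    x
  }
  out <- list(version = config$version,
              phase = config$phase,
              n_mice_per_cage = config$n_mice_per_cage,
              habituation = strip(config$habituation),
              shaping = strip(config$shaping),
              operant = strip(config$operant),
              delays = strip(config$delays),
              cages = strip(config$cages),
              agent = strip(config$agent))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.gonogo_protocol <- function(x, ...) {
  cat("<gonogo protocol> phase:", x$phase,
      "| cages:", x$cages$n_cages,
      "| mice/cage:", x$n_mice_per_cage, "\n")
  cat("  shaping: tone", x$shaping$tone_duration, "s, window",
      x$shaping$response_window_duration, "s, free water",
      x$shaping$free_water_fraction, "\n")
  cat("  operant: tone", x$operant$tone_duration, "s, window",
      x$operant$response_window_duration, "s, catch",
      signif(x$operant$catch_fraction, 3), "\n")
  cat("  delay steps:", paste(x$delays$steps, collapse = ", "), "s\n")
  invisible(x)
}

# Offsets (seconds from trial start) of the windows of one detection trial at
# a given response delay. The early window is [0, win_open): it begins at
# trial start, so it spans the pre-stimulus silence, the tone and the delay
# period -- a lick during the tone at delay > 0 is an early response.
window_geometry <- function(config, delay = config$response_delay) {
  win_open <- config$pre_stim_silence + delay
  list(tone_on = config$pre_stim_silence,
       tone_off = config$pre_stim_silence + config$tone_duration,
       win_open = win_open,
       win_close = win_open + config$response_window_duration)
}
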