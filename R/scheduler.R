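# Session availability: multi-cage rotation (for acoustic isolation between
# cages sharing a room), habituation on/off blocks, and the light/dark cycle
# the virtual mice use to modulate activity.

#' Multi-cage rotation schedule
#'
#' Cages sharing a room cannot be individually sound-isolated, so they take
#' turns: each cage is active for `active_block` minutes then inactive for
#' `inactive_block` minutes, staggered by `cage_offsets` so that (with the
#' defaults: 4 cages, 60/180 min) exactly one cage is active at any instant
#' and each cage trains 6 h per day. The 12 h dark phase of the vivarium
#' light cycle is carried here too; it modulates virtual-mouse activity but
#' never gates the engine.
#'
#' @param n_cages number of cages on the rotation.
#' @param active_block,inactive_block minutes; their sum is the rotation
#'   period.
#' @param cage_offsets minutes each cage's rotation is shifted; default
#'   `(i - 1) * active_block` for cage `i` (cage order of first activation).
#' @param dark_cycle `(start_hour, end_hour)` of the dark phase on a 24 h
#'   clock whose zero is lights-on at schedule epoch; must span 12 h.
#' @return A list of class `cage_schedule`.
#' @export
cage_schedule <- function(n_cages = 4L,
                          active_block = 60,
                          inactive_block = 180,
                          cage_offsets = NULL,
                          dark_cycle = c(12, 24)) {
  check_scalar_number(n_cages, "n_cages", lower = 1)
  check_scalar_number(active_block, "active_block", lower = 0)
  check_scalar_number(inactive_block, "inactive_block", lower = 0)
  period <- active_block + inactive_block
  check_that(period > 0, "active_block + inactive_block", "rotation period > 0")
  if (is.null(cage_offsets)) {
    cage_offsets <- (active_block * (seq_len(n_cages) - 1)) %% period
  }
  check_that(length(cage_offsets) == n_cages, "cage_offsets", "one per cage")
  check_that(all(cage_offsets >= 0 & cage_offsets < period), "cage_offsets",
             "0 <= offset < rotation period")
  check_that(length(dark_cycle) == 2L &&
               (dark_cycle[2] - dark_cycle[1]) %% 24 == 12,
             "dark_cycle", "dark phase spans 12 h")
  structure(list(n_cages = as.integer(n_cages),
                 active_block = active_block,
                 inactive_block = inactive_block,
                 period = period,
                 cage_offsets = as.numeric(cage_offsets),
                 dark_cycle = as.numeric(dark_cycle)),
            class = "cage_schedule")
}

#' Is a cage active at time t?
#'
#' A cage is active when `((t_min - offset) mod period) < active_block`,
#' where `t_min` is minutes since the schedule epoch (t = 0 is schedule
#' start). With the default 60/180 rotation this is periodic with period
#' 240 min and the four cages tile time exactly.
#'
#' @param schedule a [cage_schedule()].
#' @param cage_index zero-based cage index.
#' @param t seconds since schedule epoch (vectorized).
#' @return Logical vector.
#' @export
cage_active <- function(schedule, cage_index, t) {
  stopifnot(inherits(schedule, "cage_schedule"))
  if (cage_index < 0 || cage_index >= schedule$n_cages) {
    stop("cage_index out of range: ", cage_index, call. = FALSE)
  }
  phase_min <- (t / 60 - schedule$cage_offsets[cage_index + 1L]) %% schedule$period
  phase_min < schedule$active_block
}

#' Active-block boundaries for one cage within an interval
#'
#' Returns the `(start, end)` times (seconds) of every active block of
#' `cage_index` intersecting `[t0, t1)`, clipped to the interval.
#'
#' @inheritParams cage_active
#' @param t0,t1 interval bounds, seconds since epoch.
#' @return A two-column matrix with one row per block.
#' @export
active_blocks <- function(schedule, cage_index, t0, t1) {
  stopifnot(inherits(schedule, "cage_schedule"), t1 >= t0)
  period_s <- schedule$period * 60
  offset_s <- schedule$cage_offsets[cage_index + 1L] * 60
  active_s <- schedule$active_block * 60
  if (active_s <= 0) return(matrix(numeric(0), ncol = 2))
  k0 <- floor((t0 - offset_s) / period_s) - 1
  k1 <- ceiling((t1 - offset_s) / period_s) + 1
  starts <- offset_s + (k0:k1) * period_s
  ends <- starts + active_s
  keep <- ends > t0 & starts < t1
  cbind(pmax(starts[keep], t0), pmin(ends[keep], t1))
}

#' Is the habituation trial block active at time t?
#'
#' Habituation alternates `on_block` minutes of trials with `off_block`
#' minutes of rest: active iff `(t mod (on + off)) < on_block`.
#'
#' @param config a [habituation_config()].
#' @param t seconds since session start (vectorized).
#' @return Logical vector.
#' @export
habituation_block_active <- function(config, t) {
  stopifnot(inherits(config, "habituation_config"), all(t >= 0))
  ((t / 60) %% (config$on_block + config$off_block)) < config$on_block
}

#' Total training minutes per cage per day
#'
#' @inheritParams cage_active
#' @return Minutes of active time in 24 h (360 for the default 60/180
#'   rotation, i.e. 6 h per day).
#' @export
daily_training_minutes <- function(schedule, cage_index = 0L) {
  stopifnot(inherits(schedule, "cage_schedule"))
  if (cage_index < 0 || cage_index >= schedule$n_cages) {
    stop("cage_index out of range: ", cage_index, call. = FALSE)
  }
  if (schedule$period <= 0) return(0)
  1440 * schedule$active_block / schedule$period
}

#' Is time t in the dark phase?
#'
#' @inheritParams cage_active
#' @param t seconds since schedule epoch (vectorized); epoch is lights-on.
#' @return Logical vector, `TRUE` during the 12 h dark phase.
#' @export
is_dark <- function(schedule, t) {
  stopifnot(inherits(schedule, "cage_schedule"))
  h <- (t / 3600) %% 24
  lo <- schedule$dark_cycle[1] %% 24
  hi <- schedule$dark_cycle[2] %% 24
  if (lo < hi) h >= lo & h < hi else h >= lo | h < hi
}
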