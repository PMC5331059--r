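# Behavioral statistics: outcome rates, signal-detection d-prime, first-lick
# latency distributions, lick-rate traces, and daily learning curves.

#' Outcome rates for a trial table
#'
#' Hits and false alarms are trials where the subject licked only during the
#' response window, following a tone or during a silent catch trial
#' respectively; early responses are licks before the window opened. Two
#' denominator conventions are supported, because published rate tables are
#' often ambiguous about theirs:
#'
#' * `per_type` (default, standard signal detection): hit rate = hits /
#'   tone trials, false-alarm rate = false alarms / catch trials, early
#'   rate = early responses / all trials.
#' * `per_total`: every numerator is divided by the total trial count.
#'
#' @param trials a trial-record data frame (from a session, a program, or
#'   [events_to_trials()]).
#' @param convention `"per_type"` or `"per_total"`.
#' @return A list of class `session_rates`: counts, rates, the convention,
#'   and a `flags` character vector naming rates whose denominator was zero
#'   (those rates are `NA`).
#' @export
compute_rates <- function(trials, convention = c("per_type", "per_total")) {
  convention <- match.arg(convention)
  if (is.null(trials) || nrow(trials) == 0L) {
    stop("empty trial table", call. = FALSE)
  }
  out <- trials$outcome
  n_total <- nrow(trials)
  n_tone <- sum(!trials$is_catch)
  n_catch <- sum(trials$is_catch)
  n_hit <- sum(out == "HIT", na.rm = TRUE)
  n_fa <- sum(out == "FALSE_ALARM", na.rm = TRUE)
  n_early <- sum(out %in% c("EARLY", "EARLY_CATCH"), na.rm = TRUE)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  if (convention == "per_type") {
    hit_rate <- rate(n_hit, n_tone)
    fa_rate <- rate(n_fa, n_catch)
    early_rate <- rate(n_early, n_total)
  } else {
    hit_rate <- rate(n_hit, n_total)
    fa_rate <- rate(n_fa, n_total)
    early_rate <- rate(n_early, n_total)
  }
  flags <- c(if (is.na(hit_rate)) "hit_rate",
             if (is.na(fa_rate)) "fa_rate",
             if (is.na(early_rate)) "early_rate")
  structure(list(n_trials = n_total, n_tone = n_tone, n_catch = n_catch,
                 n_hit = n_hit, n_fa = n_fa, n_early = n_early,
                 hit_rate = hit_rate, fa_rate = fa_rate,
                 early_rate = early_rate,
                 denominator_convention = convention,
                 flags = flags %||% character(0)),
            class = "session_rates")
}

#' Signal-detection sensitivity d-prime
#'
#' `d' = Z(hit rate) - Z(false-alarm rate)`, where `Z` is the inverse of the
#' standard-normal cumulative distribution function. Rates of exactly 0 or 1
#' are replaced by `1/(2n)` or `1 - 1/(2n)` of the relevant denominator
#' (tone-trial count for the hit rate, catch-trial count for the false-alarm
#' rate) before inversion, the standard correction keeping d-prime finite.
#'
#' @param hit_rate,fa_rate proportions in `[0, 1]`.
#' @param n_tone,n_catch trial counts, required only when the corresponding
#'   rate needs the 0/1 correction.
#' @return d-prime (dimensionless), vectorized over the rates.
#' @export
compute_dprime <- function(hit_rate, fa_rate, n_tone = NULL, n_catch = NULL) {
  fix <- function(p, n, what) {
    bad <- !is.na(p) & (p < 0 | p > 1)
    if (any(bad)) stop(what, " outside [0, 1]", call. = FALSE)
    at0 <- !is.na(p) & p == 0
    at1 <- !is.na(p) & p == 1
    if (any(at0 | at1)) {
      if (is.null(n) || any(n[at0 | at1] <= 0)) {
        stop("trial count needed to correct a ", what, " of exactly 0 or 1",
             call. = FALSE)
      }
      p[at0] <- 1 / (2 * n[at0])
      p[at1] <- 1 - 1 / (2 * n[at1])
    }
    p
  }
  if (!is.null(n_tone)) n_tone <- rep_len(n_tone, length(hit_rate))
  if (!is.null(n_catch)) n_catch <- rep_len(n_catch, length(fa_rate))
  h <- fix(hit_rate, n_tone, "hit rate")
  f <- fix(fa_rate, n_catch, "false-alarm rate")
  stats::qnorm(h) - stats::qnorm(f)
}

#' First-lick latency statistics
#'
#' Latencies are the time of the first lick from trial onset, over trials
#' with at least one lick. The distribution peak is estimated as the
#' midpoint of the modal histogram bin (bins of `histogram_bin` seconds
#' anchored at zero; ties broken toward the earliest bin). With a single
#' distinct latency the peak is that value.
#'
#' @param trials a trial-record data frame (uses its `first_lick_latency`
#'   column), or a numeric vector of latencies.
#' @param histogram_bin bin width in seconds for the peak estimator.
#' @return A list: `latencies`, `median`, `peak`, `n`, and `flags`
#'   (`"no_licks"` when no trial had a lick; `median` and `peak` are then
#'   `NA`).
#' @export
first_lick_stats <- function(trials, histogram_bin = 0.1) {
  check_that(histogram_bin > 0, "histogram_bin", "> 0")
  lat <- if (is.data.frame(trials)) trials$first_lick_latency else trials
  lat <- lat[!is.na(lat)]
  if (length(lat) == 0L) {
    return(list(latencies = numeric(0), median = NA_real_, peak = NA_real_,
                n = 0L, flags = "no_licks"))
  }
  med <- stats::median(lat)
  if (length(unique(lat)) == 1L) {
    peak <- lat[1]
  } else {
    bins <- floor(lat / histogram_bin)
    tab <- table(bins)
    modal <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = earliest
    peak <- (modal + 0.5) * histogram_bin
  }
  list(latencies = lat, median = med, peak = peak, n = length(lat),
       flags = character(0))
}

#' Trial-aligned lick-probability trace
#'
#' The probability of at least one lick in each time bin relative to trial
#' start, averaged across trials (a lick PSTH on binary per-trial
#' indicators).
#'
#' @param trials a trial-record data frame with a `licks` list-column of
#'   trial-relative lick times.
#' @param bin_width bin width, seconds.
#' @param trial_filter `"tone"`, `"catch"` or `"all"`.
#' @param t_max trace length in seconds; defaults to the largest response
#'   window close among the selected trials.
#' @return A list of class `lick_rate_trace`: `bin_edges` (length bins + 1),
#'   `p_lick` per bin, `n_trials`, `trial_filter`.
#' @export
lick_rate_trace <- function(trials, bin_width = 0.1,
                            trial_filter = c("tone", "catch", "all"),
                            t_max = NULL) {
  trial_filter <- match.arg(trial_filter)
  check_that(bin_width > 0, "bin_width", "> 0")
  keep <- switch(trial_filter,
                 tone = !trials$is_catch,
                 catch = trials$is_catch,
                 all = rep(TRUE, nrow(trials)))
  trials <- trials[keep, , drop = FALSE]
  if (is.null(t_max)) {
    t_max <- suppressWarnings(max(trials$win_close, na.rm = TRUE))
    if (!is.finite(t_max)) t_max <- 0
  }
  n_bins <- max(1L, ceiling(t_max / bin_width))
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  counts <- integer(n_bins)
  n_trials <- nrow(trials)
  if (n_trials > 0L && !is.null(trials$licks)) {
    for (i in seq_len(n_trials)) {
      lk <- trials$licks[[i]]
      lk <- lk[lk >= 0 & lk < n_bins * bin_width]
      if (length(lk)) {
        b <- unique(floor(lk / bin_width)) + 1L
        counts[b] <- counts[b] + 1L
      }
    }
  }
  structure(list(bin_edges = edges,
                 p_lick = if (n_trials > 0) counts / n_trials else rep(0, n_bins),
                 n_trials = n_trials,
                 trial_filter = trial_filter),
            class = "lick_rate_trace")
}

#' Full per-session summary
#'
#' Combines [compute_rates()], [compute_dprime()] and [first_lick_stats()]
#' into the standard session summary.
#'
#' @inheritParams compute_rates
#' @inheritParams first_lick_stats
#' @return A list of class `session_summary`.
#' @export
session_summary <- function(trials, convention = c("per_type", "per_total"),
                            histogram_bin = 0.1) {
  r <- compute_rates(trials, convention)
  dp <- if (!is.na(r$hit_rate) && !is.na(r$fa_rate)) {
    compute_dprime(r$hit_rate, r$fa_rate, r$n_tone, r$n_catch)
  } else NA_real_
  fl <- first_lick_stats(trials, histogram_bin)
  structure(c(unclass(r),
              list(dprime = dp,
                   median_first_lick_latency = fl$median,
                   peak_first_lick_latency = fl$peak)),
            class = "session_summary")
}

#' @export
print.session_summary <- function(x, ...) {
  cat(sprintf("<session summary> %d trials (%d tone, %d catch), convention %s\n",
              x$n_trials, x$n_tone, x$n_catch, x$denominator_convention))
  cat(sprintf("  hit %.3f | FA %s | early %.3f | d' %s\n",
              x$hit_rate,
              ifelse(is.na(x$fa_rate), "NA", sprintf("%.4f", x$fa_rate)),
              x$early_rate,
              ifelse(is.na(x$dprime), "NA", sprintf("%.3f", x$dprime))))
  cat(sprintf("  first-lick latency: median %s s, peak %s s\n",
              format(x$median_first_lick_latency),
              format(x$peak_first_lick_latency)))
  invisible(x)
}

#' Daily learning curve
#'
#' One row per training day: the required response delay, peak and median
#' first-lick latency, and outcome rates, averaged across cages (each cage
#' contributes its own per-day statistic; rates follow `convention`).
#' False-alarm rates are `NA` on days without catch trials (they are only
#' measured once catch trials are introduced).
#'
#' @param trials a trial-record data frame covering one or more cages and
#'   days (needs `day_index`, `cage_id` columns).
#' @inheritParams compute_rates
#' @inheritParams first_lick_stats
#' @return A data frame of class `learning_curve`.
#' @export
learning_curve <- function(trials, convention = "per_type",
                           histogram_bin = 0.1) {
  stopifnot(!is.null(trials$day_index))
  days <- sort(unique(trials$day_index))
  rows <- lapply(days, function(d) {
    td <- trials[trials$day_index == d, , drop = FALSE]
    per_cage <- lapply(split(td, td$cage_id), function(tc) {
      fl <- first_lick_stats(tc, histogram_bin)
      r <- compute_rates(tc, convention)
      c(peak = fl$peak, median = fl$median, delay = max(tc$delay, na.rm = TRUE),
        hit = r$hit_rate, early = r$early_rate, fa = r$fa_rate,
        n = r$n_trials)
    })
    m <- do.call(rbind, per_cage)
    data.frame(day_index = d,
               delay = mean(m[, "delay"], na.rm = TRUE),
               peak_latency = mean(m[, "peak"], na.rm = TRUE),
               median_latency = mean(m[, "median"], na.rm = TRUE),
               hit_rate = mean(m[, "hit"], na.rm = TRUE),
               early_rate = mean(m[, "early"], na.rm = TRUE),
               fa_rate = if (all(is.na(m[, "fa"]))) NA_real_
                         else mean(m[, "fa"], na.rm = TRUE),
               n_trials = sum(m[, "n"]),
               n_cages = nrow(m))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("learning_curve", class(out))
  out
}

#' Pearson correlation between two learning-curve fields
#'
#' Two-sided p-value via the t-distribution transform (the classical test
#' behind `cor.test`). Days where either field is `NA` are dropped; a
#' constant series leaves `r` undefined (flagged).
#'
#' @param curve a [learning_curve()] (or any data frame).
#' @param x_field,y_field column names.
#' @return A list: `r`, `p`, `n`, `flags`.
#' @export
correlate_curve <- function(curve, x_field, y_field) {
  x <- curve[[x_field]]; y <- curve[[y_field]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), flags = "too_few_days"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), flags = "constant_series"))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       flags = character(0))
}

#' Reference final-session statistics of a group-trained cohort
#'
#' A benchmark table of per-cage single-session statistics from a four-cage,
#' group-trained tone-detection cohort (three mice per cage, ad libitum
#' home-cage training): trial counts, hit / false-alarm / early percentages,
#' d-prime, and median first-lick latency. Shipped as plain CSV in
#' `extdata`; used as a fixture by the analysis layer.
#'
#' @return A data frame with one row per cage.
#' @export
reference_final_sessions <- function() {
  path <- system.file("extdata", "reference_final_sessions.csv",
                      package = "gonogo")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Summary statistics of a per-cage rate table
#'
#' Computes the cohort-level quantities usually quoted from a final-session
#' rate table: the ratio of the mean hit percentage to the mean early
#' percentage (how much likelier a hit is than an early response) and the
#' mean d-prime across cages.
#'
#' @param sessions a data frame with columns `hit_pct`, `early_pct` and
#'   `dprime` (see [reference_final_sessions()]).
#' @return A list: `hit_early_ratio`, `mean_dprime`, `mean_hit_pct`,
#'   `mean_early_pct`, `mean_fa_pct`.
#' @export
summarize_final_sessions <- function(sessions = reference_final_sessions()) {
  list(hit_early_ratio = mean(sessions$hit_pct) / mean(sessions$early_pct),
       mean_dprime = mean(sessions$dprime),
       mean_hit_pct = mean(sessions$hit_pct),
       mean_early_pct = mean(sessions$early_pct),
       mean_fa_pct = mean(sessions$fa_pct))
}
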