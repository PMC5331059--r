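# On-disk event format: line-delimited JSON, one event per line, stable
# field order, a schema-version header record on the first line. Times are
# seconds on the session clock at fixed 1 ms resolution (lick sensors work
# at millisecond scale). A flat CSV trial-table export serves spreadsheet
# users; the JSONL stream is the lossless primary format.

events_schema_version <- function() "gonogo-events/1"

event_types <- function() {
  c("SESSION_START", "PHASE_CHANGE", "CAGE_ACTIVE", "CAGE_INACTIVE",
    "TRIAL_START", "TONE_ON", "TONE_OFF", "LICK", "REWARD_ON", "REWARD_OFF",
    "TIMEOUT_START", "TRIAL_END")
}

json_str <- function(x) {
  paste0('"', gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x)), '"')
}

#' Write an event stream to a JSONL file
#'
#' One JSON object per line in a fixed field order (`t`, `cage_id`,
#' `mouse_id`, `event_type`, `trial_id`, `day_index`, `phase`, `is_catch`,
#' `delay`, `win_open`, `win_close`, `free_water`, `outcome`, `rewarded`,
#' `timeout_applied`, `first_lick_latency`); fields that are `NA` for an
#' event are omitted. The first line is a header record carrying the schema
#' version. Timestamps are written with fixed millisecond precision, so a
#' write/read round trip is lossless and identical inputs give
#' byte-identical files.
#'
#' @param events an event data frame (as produced by [run_session()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events))
  if (is.unsorted(events$t)) {
    stop("event timestamps must be non-decreasing", call. = FALSE)
  }
  n <- nrow(events)
  piece <- function(name, x, render) {
    ifelse(is.na(x), NA_character_, paste0('"', name, '":', render(x)))
  }
  num3 <- function(x) sprintf("%.3f", x)
  int <- function(x) sprintf("%d", as.integer(x))
  boolean <- function(x) ifelse(x, "true", "false")
  cols <- list(
    piece("t", events$t, num3),
    piece("cage_id", events$cage_id, int),
    piece("mouse_id", events$mouse_id, int),
    piece("event_type", events$event_type, json_str),
    piece("trial_id", events$trial_id, int),
    piece("day_index", events$day_index, int),
    piece("phase", events$phase, json_str),
    piece("is_catch", events$is_catch, boolean),
    piece("delay", events$delay, num3),
    piece("win_open", events$win_open, num3),
    piece("win_close", events$win_close, num3),
    piece("free_water", events$free_water, boolean),
    piece("outcome", events$outcome, json_str),
    piece("rewarded", events$rewarded, boolean),
    piece("timeout_applied", events$timeout_applied, boolean),
    piece("first_lick_latency", events$first_lick_latency, num3))
  cols <- cols[!vapply(cols, is.null, TRUE)]
  m <- do.call(cbind, cols)
  lines <- apply(m, 1L, function(r) {
    paste0("{", paste(r[!is.na(r)], collapse = ","), "}")
  })
  header <- paste0('{"schema":', json_str(events_schema_version()),
                   ',"n_events":', n, "}")
  con <- file(path, open = "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  writeLines(c(header, lines), con, sep = "\n")
  invisible(path)
}

#' Read an event stream from a JSONL file
#'
#' Validates the schema header, parses one event per line, and enforces
#' non-decreasing timestamps. A malformed line or a timestamp regression is
#' reported with its line number.
#'
#' @param path path to a file written by [write_events()].
#' @return An event data frame.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty event file: ", path, call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
  if (is.null(header) || is.null(header$schema)) {
    stop("line 1: missing schema header record", call. = FALSE)
  }
  if (!identical(header$schema, events_schema_version())) {
    stop("unsupported event schema: ", header$schema, call. = FALSE)
  }
  body <- lines[-1]
  template <- event_template()
  if (length(body) == 0L) {
    df <- as.data.frame(template, stringsAsFactors = FALSE)[0, ]
    return(df)
  }
  parsed <- tryCatch(
    jsonlite::stream_in(textConnection(body), verbose = FALSE),
    error = function(e) NULL)
  if (is.null(parsed)) {
    # rescan to report the offending line
    for (i in seq_along(body)) {
      ok <- tryCatch({ jsonlite::fromJSON(body[i]); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop("line ", i + 1L, ": malformed event record", call. = FALSE)
    }
    stop("malformed event file: ", path, call. = FALSE)
  }
  for (nm in names(template)) {
    if (is.null(parsed[[nm]])) parsed[[nm]] <- rep(template[[nm]], nrow(parsed))
  }
  parsed <- parsed[names(template)]
  parsed$cage_id <- as.integer(parsed$cage_id)
  parsed$mouse_id <- as.integer(parsed$mouse_id)
  parsed$trial_id <- as.integer(parsed$trial_id)
  parsed$day_index <- as.integer(parsed$day_index)
  bad <- which(diff(parsed$t) < 0)
  if (length(bad)) {
    stop("line ", bad[1] + 2L, ": timestamp regression", call. = FALSE)
  }
  unknown <- setdiff(unique(parsed$event_type), event_types())
  if (length(unknown)) {
    stop("unknown event type(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  parsed
}

#' Structural validation of an event stream
#'
#' Checks the invariants of a well-formed log: non-decreasing timestamps,
#' every `TRIAL_START` paired with a `TRIAL_END` of the same trial, and no
#' `TONE_ON` on catch trials.
#'
#' @param events an event data frame.
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_events <- function(events) {
  if (is.unsorted(events$t)) stop("timestamp regression", call. = FALSE)
  for (cage in unique(events$cage_id)) {
    ec <- events[events$cage_id == cage, , drop = FALSE]
    starts <- ec$trial_id[ec$event_type == "TRIAL_START"]
    ends <- ec$trial_id[ec$event_type == "TRIAL_END"]
    if (!setequal(starts, ends) || anyDuplicated(starts) || anyDuplicated(ends)) {
      stop("unpaired TRIAL_START/TRIAL_END markers (cage ", cage, ")",
           call. = FALSE)
    }
    catch_ids <- ec$trial_id[ec$event_type == "TRIAL_START" &
                               !is.na(ec$is_catch) & ec$is_catch]
    tone_ids <- ec$trial_id[ec$event_type == "TONE_ON"]
    if (length(intersect(catch_ids, tone_ids))) {
      stop("TONE_ON present on a catch trial (cage ", cage, ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Rebuild the trial table from an event stream
#'
#' One trial record per `TRIAL_START`/`TRIAL_END` pair, grouped per cage for
#' mixed-cage files. Licks are assigned to the open trial by timestamp. For
#' detection trials the outcome is recomputed from the reconstructed windows
#' via [classify_trial()] and checked against the logged outcome; a mismatch
#' is a consistency error.
#'
#' @param events an event data frame (validated with [validate_events()]).
#' @return A trial-record data frame matching the engine's own table.
#' @export
events_to_trials <- function(events) {
  validate_events(events)
  out <- list()
  for (cage in sort(unique(events$cage_id))) {
    ec <- events[events$cage_id == cage, , drop = FALSE]
    st <- ec[ec$event_type == "TRIAL_START", , drop = FALSE]
    en <- ec[ec$event_type == "TRIAL_END", , drop = FALSE]
    if (nrow(st) == 0L) next
    en <- en[match(st$trial_id, en$trial_id), , drop = FALSE]
    lick <- ec[ec$event_type == "LICK", , drop = FALSE]
    tr <- new_collector(trial_template(), max(16L, nrow(st)))
    for (i in seq_len(nrow(st))) {
      t0 <- st$t[i]; t1 <- en$t[i]
      in_trial <- lick$t >= t0 & lick$t <= t1
      lt <- lick$t[in_trial]; lm <- lick$mouse_id[in_trial]
      outcome <- en$outcome[i]
      if (!is.na(st$win_open[i])) {
        spec <- structure(list(trial_id = st$trial_id[i], t_start = t0,
                               is_catch = isTRUE(st$is_catch[i]),
                               delay = st$delay[i],
                               win_open = st$win_open[i],
                               win_close = st$win_close[i],
                               free_water = isTRUE(st$free_water[i])),
                          class = "trial_spec")
        chk <- classify_trial(spec, lt)
        if (!is.na(outcome) && !identical(chk$label, outcome)) {
          stop("consistency error: trial ", st$trial_id[i], " (cage ", cage,
               ") logged as ", outcome, " but recomputes as ", chk$label,
               call. = FALSE)
        }
        outcome <- chk$label
      }
      collector_push(tr, list(
        trial_id = st$trial_id[i], cage_id = cage,
        day_index = st$day_index[i], phase = st$phase[i],
        t_start = t0, is_catch = isTRUE(st$is_catch[i]),
        delay = st$delay[i], win_open = st$win_open[i],
        win_close = st$win_close[i], free_water = isTRUE(st$free_water[i]),
        outcome = outcome, rewarded = en$rewarded[i],
        timeout_applied = en$timeout_applied[i],
        first_lick_latency = if (length(lt)) round(lt[1] - t0, 3) else NA_real_,
        n_licks = length(lt),
        licks = list(round(lt - t0, 3)),
        lick_mice = list(lm)))
    }
    out[[length(out) + 1L]] <- collector_df(tr)
  }
  if (length(out) == 0L) {
    df <- as.data.frame(trial_template(), stringsAsFactors = FALSE)[0, ]
    df$licks <- list(); df$lick_mice <- list()
    return(df)
  }
  do.call(rbind, out)
}

#' Export / import the trial table as flat CSV
#'
#' The list-columns (`licks`, `lick_mice`) are serialized as
#' semicolon-joined strings so the file stays a plain one-row-per-trial CSV.
#' `read_trials()` restores them; a write/read round trip preserves all
#' shared fields with the JSONL events.
#'
#' @param trials a trial-record data frame.
#' @param path CSV path.
#' @return `path` invisibly (`write_trials`); the trial data frame
#'   (`read_trials`).
#' @export
write_trials <- function(trials, path) {
  df <- trials
  if (!is.null(df$licks)) {
    df$licks <- vapply(df$licks, function(x) paste(sprintf("%.3f", x),
                                                   collapse = ";"), "")
  }
  if (!is.null(df$lick_mice)) {
    df$lick_mice <- vapply(df$lick_mice, function(x) paste(x, collapse = ";"), "")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$licks)) {
    df$licks <- lapply(strsplit(as.character(df$licks), ";", fixed = TRUE),
                       function(x) as.numeric(x[nzchar(x)]))
  }
  if (!is.null(df$lick_mice)) {
    df$lick_mice <- lapply(strsplit(as.character(df$lick_mice), ";", fixed = TRUE),
                           function(x) as.integer(x[nzchar(x)]))
  }
  df
}
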