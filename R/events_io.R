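#' Read a posture-event file
#'
#' Parses an event-level export from a thigh-worn posture monitor into a
#' tidy event table. Two column conventions ("dialects") are supported:
#'
#' * `"activpal_events"`: columns `Time` (ISO 8601 date-time or Excel serial
#'   day number), `Interval` (event duration in seconds), `ActivityCode`
#'   (0 = sedentary, 1 = standing, 2 = stepping) and `CumulativeStepCount`.
#'   Step cadence is derived from successive cumulative step counts.
#' * `"plain"`: columns `start` (ISO 8601), `duration_s`, `activity`
#'   (`sedentary`/`standing`/`stepping`) and `cadence` (steps/min).
#'
#' Timestamps are treated as a naive local clock (stored as UTC); event
#' extent is always governed by the recorded duration in seconds, never by
#' wall-clock subtraction, so daylight-saving transitions cannot corrupt
#' durations. Events are sorted by start time; an event overlapping its
#' successor is truncated at the successor's start with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Column convention, see Details.
#' @param class_map Optional named character vector mapping non-standard
#'   activity codes to `sedentary`/`standing`/`stepping`. Unknown codes
#'   without a mapping are an error.
#' @return A tibble with columns `start` (POSIXct), `duration` (seconds),
#'   `activity` (factor) and `cadence` (steps/min, 0 unless stepping),
#'   sorted and non-overlapping.
#' @export
read_events <- function(path, dialect = c("activpal_events", "plain"),
                        class_map = NULL) {
  dialect <- match.arg(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- switch(dialect,
    activpal_events = c("Time", "Interval", "ActivityCode", "CumulativeStepCount"),
    plain = c("start", "duration_s", "activity", "cadence")
  )
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "event file %s is missing required column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ), class = "mbsced_format_error")
  }
  if (nrow(raw) == 0) {
    return(tibble(
      start = as.POSIXct(character(), tz = "UTC"),
      duration = numeric(), activity = activity_factor(character()),
      cadence = numeric()
    ))
  }

  if (dialect == "activpal_events") {
    start <- parse_event_time(raw$Time)
    duration <- as.numeric(raw$Interval)
    code <- raw$ActivityCode
    std <- c(`0` = "sedentary", `1` = "standing", `2` = "stepping")
    map <- c(std, class_map)
    activity <- unname(map[code])
    if (anyNA(activity)) {
      bad <- which(is.na(activity))[1]
      abort(sprintf(
        "unknown activity code '%s' at row %d (supply class_map to translate it)",
        code[bad], bad
      ), class = "mbsced_format_error")
    }
    cum <- as.numeric(raw$CumulativeStepCount)
    steps <- diff(c(0, cum))
    cadence <- ifelse(activity == "stepping" & duration > 0,
                      steps / (duration / 60), 0)
  } else {
    start <- parse_event_time(raw$start)
    duration <- as.numeric(raw$duration_s)
    activity <- raw$activity
    bad_class <- setdiff(unique(activity), c("sedentary", "standing", "stepping"))
    if (length(bad_class) > 0) {
      abort(sprintf("unknown activity class(es): %s",
                    paste(bad_class, collapse = ", ")),
            class = "mbsced_format_error")
    }
    cadence <- as.numeric(raw$cadence)
    cadence[activity != "stepping"] <- 0
  }

  bad_row <- which(is.na(start) | is.na(duration))
  if (length(bad_row) > 0) {
    abort(sprintf("unparseable timestamp or duration at row %d of %s",
                  bad_row[1], path), class = "mbsced_format_error")
  }
  if (any(duration <= 0)) {
    abort(sprintf("non-positive event duration at row %d",
                  which(duration <= 0)[1]), class = "mbsced_format_error")
  }

  ev <- tibble(start = start, duration = duration,
               activity = activity_factor(activity), cadence = cadence)
  ev <- arrange(ev, start)
  resolve_overlaps(ev)
}

activity_factor <- function(x) {
  factor(x, levels = c("sedentary", "standing", "stepping"))
}

parse_event_time <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) {
    # Excel serial day number (days since 1899-12-30); round to the
    # millisecond to undo double-precision jitter of the day fraction
    secs <- round((num - 25569) * 86400, 3)
    return(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"))
  }
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

# Truncate any event that runs past the start of its successor. The
# tolerance (10 microseconds) absorbs timestamp-precision jitter without
# masking genuine overlaps, which are orders of magnitude larger.
resolve_overlaps <- function(ev, tol = 1e-5) {
  if (nrow(ev) < 2) {
    return(ev)
  }
  ends <- as.numeric(ev$start) + ev$duration
  nxt <- c(as.numeric(ev$start)[-1], Inf)
  over <- ends > nxt + tol
  if (any(over)) {
    new_dur <- nxt[over] - as.numeric(ev$start)[over]
    if (any(new_dur <= 0)) {
      abort("two events share a start time; cannot resolve overlap",
            class = "mbsced_format_error")
    }
    ev$duration[over] <- new_dur
    warn(sprintf("truncated %d overlapping event(s)", sum(over)))
  }
  ev
}

#' Write a posture-event table
#'
#' @param events Event tibble as returned by [read_events()].
#' @param path Output CSV path.
#' @param dialect `"plain"` (default; round-trips through [read_events()]
#'   to microsecond precision) or `"activpal_events"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = c("plain", "activpal_events")) {
  dialect <- match.arg(dialect)
  # %OS6 truncates fractional seconds; nudge by half a microsecond so the
  # written timestamp is the rounded value
  fmt_start <- function(x) {
    format(x + 5e-7, "%Y-%m-%dT%H:%M:%OS6", tz = "UTC")
  }
  if (dialect == "plain") {
    out <- tibble(
      start = fmt_start(events$start),
      duration_s = events$duration,
      activity = as.character(events$activity),
      cadence = events$cadence
    )
  } else {
    steps <- ifelse(events$activity == "stepping",
                    events$cadence * events$duration / 60, 0)
    out <- tibble(
      Time = fmt_start(events$start),
      Interval = events$duration,
      ActivityCode = c(sedentary = 0L, standing = 1L, stepping = 2L)[
        as.character(events$activity)],
      CumulativeStepCount = cumsum(steps)
    )
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a wake/sleep diary
#'
#' Diaries record, per calendar date, the time the participant got out of
#' bed and the time they went to sleep; they define the waking window used
#' to restrict posture events to waking hours. A bed time at or before the
#' rise time is interpreted as falling on the next day.
#'
#' @param path CSV with columns `date` (YYYY-MM-DD), `rise_time` (HH:MM),
#'   `bed_time` (HH:MM) and optionally `participant_id`.
#' @return A tibble with one row per date: `participant_id`, `date`,
#'   `rise_time`, `bed_time`, `window_hours`.
#' @export
read_diary <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  needed <- c("date", "rise_time", "bed_time")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("diary %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")),
          class = "mbsced_format_error")
  }
  pid <- if ("participant_id" %in% names(raw)) raw$participant_id else NA_character_
  date <- as.Date(raw$date)
  if (anyNA(date) && nrow(raw) > 0) {
    abort(sprintf("unparseable date at row %d", which(is.na(date))[1]),
          class = "mbsced_format_error")
  }
  rise <- parse_clock(raw$rise_time)
  bed <- parse_clock(raw$bed_time)
  if (anyNA(rise) || anyNA(bed)) {
    abort("unparseable rise or bed time (expect HH:MM)",
          class = "mbsced_format_error")
  }
  window_hours <- (bed - rise) / 3600
  window_hours[window_hours <= 0] <- window_hours[window_hours <= 0] + 24
  if (any(window_hours <= 0 | window_hours > 24)) {
    abort("waking window must be in (0, 24] hours", class = "mbsced_format_error")
  }
  key <- paste(pid, date)
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate diary entry for date %s",
                  date[duplicated(key)][1]), class = "mbsced_format_error")
  }
  tibble(participant_id = pid, date = date,
         rise_time = raw$rise_time, bed_time = raw$bed_time,
         window_hours = window_hours)
}

# seconds since midnight from "HH:MM" or "HH:MM:SS"
parse_clock <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2 || length(p) > 3 || anyNA(p)) {
      return(NA_real_)
    }
    p[1] * 3600 + p[2] * 60 + if (length(p) == 3) p[3] else 0
  }, numeric(1))
}

#' Partition a posture-event stream into waking days
#'
#' Clips events to the per-day waking window defined by the diary. An event
#' spanning a window boundary is split and only the in-window part is kept
#' (class preserved), so waking time is conserved. Dates with recorded
#' events but no diary entry are either dropped with a warning or, when
#' `fallback = TRUE`, given a heuristic window: the longest sedentary event
#' overlapping 00:00-06:00 is treated as the night's sleep. Diaries are
#' authoritative whenever present; every fallback day is reported.
#'
#' @param events Event tibble from [read_events()].
#' @param diary Diary tibble from [read_diary()].
#' @param fallback Use the heuristic sleep detector for uncovered dates?
#' @return A tibble with one row per waking day: `date`, `window_start`,
#'   `window_end`, `window_hours`, `wear_hours` (sum of in-window event
#'   time) and an `events` list-column of clipped event tibbles.
#' @export
split_waking_days <- function(events, diary, fallback = FALSE) {
  ev_dates <- event_dates(events)
  if (nrow(diary) == 0 && !fallback) {
    abort(sprintf("no diary entries and fallback disabled; uncovered dates: %s",
                  paste(ev_dates, collapse = ", ")))
  }
  uncovered <- setdiff(as.character(ev_dates), as.character(diary$date))
  window_hours <- if ("window_hours" %in% names(diary)) diary$window_hours
  if (is.null(window_hours)) {
    window_hours <- (parse_clock(diary$bed_time) - parse_clock(diary$rise_time)) / 3600
    window_hours[window_hours <= 0] <- window_hours[window_hours <= 0] + 24
  }
  windows <- tibble(
    date = diary$date,
    window_start = as.POSIXct(paste(diary$date), tz = "UTC") +
      parse_clock(diary$rise_time),
    source = "diary"
  )
  windows$window_end <- windows$window_start + window_hours * 3600

  if (length(uncovered) > 0) {
    if (fallback) {
      fb <- bind_rows(lapply(as.Date(uncovered), fallback_window, events = events))
      if (nrow(fb) > 0) {
        inform(sprintf("fallback waking window used for %d date(s): %s",
                       nrow(fb), paste(fb$date, collapse = ", ")))
        windows <- bind_rows(windows, fb)
      }
      dropped <- setdiff(uncovered, as.character(fb$date))
      if (length(dropped) > 0) {
        warn(sprintf("dropped %d date(s) where no sleep period could be found: %s",
                     length(dropped), paste(dropped, collapse = ", ")))
      }
    } else {
      warn(sprintf("dropped %d date(s) with no diary entry: %s",
                   length(uncovered), paste(uncovered, collapse = ", ")))
    }
  }

  windows <- arrange(windows, .data$window_start)
  days <- lapply(seq_len(nrow(windows)), function(i) {
    clipped <- clip_events(events, windows$window_start[i], windows$window_end[i])
    tibble(
      date = windows$date[i],
      window_start = windows$window_start[i],
      window_end = windows$window_end[i],
      window_hours = as.numeric(windows$window_end[i] - windows$window_start[i],
                                units = "hours"),
      wear_hours = sum(clipped$duration) / 3600,
      events = list(clipped)
    )
  })
  bind_rows(days)
}

event_dates <- function(events) {
  if (nrow(events) == 0) {
    return(as.Date(character()))
  }
  # a date counts only if the event overlaps it with positive measure, so
  # an event ending exactly at midnight does not claim the next day
  ends <- events$start + events$duration - 1e-3
  sort(unique(c(as.Date(events$start, tz = "UTC"), as.Date(ends, tz = "UTC"))))
}

clip_events <- function(events, ws, we) {
  if (nrow(events) == 0) {
    return(events)
  }
  start_s <- as.numeric(events$start)
  end_s <- start_s + events$duration
  keep <- start_s < as.numeric(we) & end_s > as.numeric(ws)
  ev <- events[keep, , drop = FALSE]
  if (nrow(ev) == 0) {
    return(ev)
  }
  new_start <- pmax(as.numeric(ev$start), as.numeric(ws))
  new_end <- pmin(as.numeric(ev$start) + ev$duration, as.numeric(we))
  ev$start <- as.POSIXct(new_start, origin = "1970-01-01", tz = "UTC")
  ev$duration <- new_end - new_start
  ev[ev$duration > 0, , drop = FALSE]
}

# Heuristic wake window for a date without a diary entry: the longest
# sedentary event overlapping the small hours marks the night's sleep.
fallback_window <- function(d, events) {
  rise_ev <- longest_sed_overlapping(events, as.POSIXct(paste(d), tz = "UTC"),
                                     as.POSIXct(paste(d), tz = "UTC") + 6 * 3600)
  bed_ev <- longest_sed_overlapping(events, as.POSIXct(paste(d + 1), tz = "UTC"),
                                    as.POSIXct(paste(d + 1), tz = "UTC") + 6 * 3600)
  day_start <- as.POSIXct(paste(d), tz = "UTC")
  rise <- if (is.null(rise_ev)) {
    first <- events$start[events$start >= day_start][1]
    if (is.na(first)) return(tibble())
    max(first, day_start)
  } else {
    min(rise_ev$start + rise_ev$duration, day_start + 24 * 3600)
  }
  bed <- if (is.null(bed_ev)) {
    ends <- events$start + events$duration
    on_day <- ends[events$start < day_start + 24 * 3600 & ends > rise]
    if (length(on_day) == 0) return(tibble())
    min(max(on_day), day_start + 24 * 3600)
  } else {
    bed_ev$start
  }
  wh <- as.numeric(bed - rise, units = "hours")
  if (is.na(wh) || wh <= 0 || wh > 24) {
    return(tibble())
  }
  tibble(date = d, window_start = rise, window_end = bed, source = "fallback")
}

longest_sed_overlapping <- function(events, ws, we) {
  sed <- events[events$activity == "sedentary", , drop = FALSE]
  if (nrow(sed) == 0) {
    return(NULL)
  }
  ends <- sed$start + sed$duration
  hit <- sed$start < we & ends > ws
  if (!any(hit)) {
    return(NULL)
  }
  sed <- sed[hit, , drop = FALSE]
  sed[which.max(sed$duration), , drop = FALSE]
}
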