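#' Sedentary bouts within one waking day
#'
#' A sedentary bout is a maximal run of consecutive sedentary events:
#' adjacent sedentary events with no time gap are merged into one bout, and
#' any upright event or in-window gap terminates the bout. No tolerance is
#' applied across brief interruptions -- event streams from posture monitors
#' are already smoothed by the device, so even a seconds-long upright event
#' is a genuine break in sitting.
#'
#' @param events Clipped event tibble for one waking day (sorted).
#' @param gap_tol Numerical tolerance (seconds) when testing contiguity.
#' @return A tibble of bouts with columns `start` and `duration` (seconds).
#' @export
sedentary_bouts <- function(events, gap_tol = 1e-6) {
  if (nrow(events) == 0) {
    return(tibble(start = as.POSIXct(character(), tz = "UTC"), duration = numeric()))
  }
  sed <- events$activity == "sedentary"
  start_s <- as.numeric(events$start)
  end_s <- start_s + events$duration
  # a sedentary event opens a new bout unless the previous event was also
  # sedentary and abuts it in time
  prev_sed <- c(FALSE, sed[-length(sed)])
  prev_end <- c(-Inf, end_s[-length(end_s)])
  new_bout <- sed & !(prev_sed & (start_s - prev_end) <= gap_tol)
  bout_id <- cumsum(new_bout)
  bout_id[!sed] <- NA
  keep <- !is.na(bout_id)
  if (!any(keep)) {
    return(tibble(start = as.POSIXct(character(), tz = "UTC"), duration = numeric()))
  }
  agg <- tapply(events$duration[keep], bout_id[keep], sum)
  first <- tapply(start_s[keep], bout_id[keep], min)
  tibble(
    start = as.POSIXct(as.numeric(first), origin = "1970-01-01", tz = "UTC"),
    duration = as.numeric(agg)
  )
}

#' Daily movement-behavior metrics
#'
#' Computes the daily outcomes of a movement-behavior analysis from one
#' waking day:
#'
#' * `sedentary_hours`: total sedentary event time.
#' * `fragmentation_index`: sedentary bout count per sedentary hour; higher
#'   values mean sitting is interrupted more often. A rise of 1.1 at 10 h of
#'   daily sitting corresponds to about 11 additional interruptions.
#' * `prolonged_bout_fraction`: proportion of sedentary time accumulated in
#'   bouts strictly longer than 30 min.
#' * `mvpa_minutes`: stepping time at or above `mvpa_cadence` (a cadence
#'   proxy for moderate-to-vigorous activity on class-based monitors).
#' * `lpa_hours`: standing plus stepping below the cadence threshold.
#' * `pct_waking_sedentary`, `sleep_hours` (24 minus the waking window) and
#'   a `valid` flag based on minimum daily wear.
#'
#' @param day One row of the waking-day tibble from [split_waking_days()]
#'   (or a list with `events`, `window_hours`, `wear_hours`).
#' @param mvpa_cadence Steps/min at or above which stepping counts as MVPA.
#' @param min_wear_hours Minimum daily wear for a valid day.
#' @return A one-row tibble of metrics.
#' @export
day_metrics <- function(day, mvpa_cadence = 100, min_wear_hours = 10) {
  events <- if (is.data.frame(day$events[[1]])) day$events[[1]] else day$events
  window_hours <- day$window_hours[[1]]
  wear_hours <- day$wear_hours[[1]]
  if (is.na(wear_hours) || wear_hours <= 0) {
    abort("day has no wear time (wear_hours <= 0)")
  }
  sed_s <- sum(events$duration[events$activity == "sedentary"])
  bouts <- sedentary_bouts(events)
  sed_h <- sed_s / 3600
  fi <- if (sed_h > 0) nrow(bouts) / sed_h else 0
  prolonged <- if (sed_s > 0) sum(bouts$duration[bouts$duration > 30 * 60]) / sed_s else 0
  stepping <- events$activity == "stepping"
  mvpa_s <- sum(events$duration[stepping & events$cadence >= mvpa_cadence])
  lpa_s <- sum(events$duration[events$activity == "standing"]) +
    sum(events$duration[stepping & events$cadence < mvpa_cadence])
  tibble(
    sedentary_hours = sed_h,
    fragmentation_index = fi,
    prolonged_bout_fraction = prolonged,
    lpa_hours = lpa_s / 3600,
    mvpa_minutes = mvpa_s / 60,
    pct_waking_sedentary = 100 * sed_h / window_hours,
    sleep_hours = 24 - window_hours,
    valid = wear_hours >= min_wear_hours
  )
}

#' Metrics for every waking day of a recording
#'
#' @param waking_days Waking-day tibble from [split_waking_days()].
#' @inheritParams day_metrics
#' @return A tibble with one row per day: `date`, `window_hours`,
#'   `wear_hours` and the [day_metrics()] columns.
#' @export
days_metrics <- function(waking_days, mvpa_cadence = 100, min_wear_hours = 10) {
  rows <- lapply(seq_len(nrow(waking_days)), function(i) {
    d <- waking_days[i, ]
    if (d$wear_hours <= 0) {
      m <- day_metrics(list(events = d$events[[1]], window_hours = d$window_hours,
                            wear_hours = 1e-9),
                       mvpa_cadence, min_wear_hours)
      m$valid <- FALSE
    } else {
      m <- day_metrics(d, mvpa_cadence, min_wear_hours)
    }
    dplyr::bind_cols(d[, c("date", "window_hours", "wear_hours")], m)
  })
  bind_rows(rows)
}

#' Screen a week of monitoring against the sedentary-pattern criterion
#'
#' Eligibility for a sedentary-behavior intervention requires a mean of at
#' least 9.5 h of daily sedentary time over the screening week AND at least
#' one of: more than half of sedentary time accumulated in bouts longer
#' than 30 min, or weekly moderate-to-vigorous activity below the 150-min
#' guideline.
#'
#' @param metrics Daily metrics tibble from [days_metrics()] covering about
#'   one week.
#' @param guideline_minutes Weekly MVPA guideline (default 150).
#' @param min_valid_days Minimum number of valid days required.
#' @param sedentary_threshold Mean daily sedentary hours cutoff.
#' @param prolonged_threshold Mean prolonged-bout fraction cutoff.
#' @return A list of class `mb_eligibility` with the component criteria and
#'   the overall `eligible` flag. Weekly MVPA is the sum over valid days
#'   rescaled to 7 days when fewer than 7 are valid.
#' @export
screen_eligibility <- function(metrics, guideline_minutes = 150,
                               min_valid_days = 4,
                               sedentary_threshold = 9.5,
                               prolonged_threshold = 0.5) {
  valid <- metrics[metrics$valid, , drop = FALSE]
  if (nrow(valid) < min_valid_days) {
    abort(sprintf("only %d valid day(s); at least %d required for screening",
                  nrow(valid), min_valid_days))
  }
  mean_sed <- mean(valid$sedentary_hours)
  prolonged_met <- mean(valid$prolonged_bout_fraction) > prolonged_threshold
  mvpa_week <- sum(valid$mvpa_minutes) * 7 / nrow(valid)
  guideline_not_met <- mvpa_week < guideline_minutes
  res <- list(
    mean_daily_sedentary_hours = mean_sed,
    prolonged_criterion_met = prolonged_met,
    mvpa_week_minutes = mvpa_week,
    guideline_not_met = guideline_not_met,
    eligible = mean_sed >= sedentary_threshold &&
      (prolonged_met || guideline_not_met),
    n_valid_days = nrow(valid)
  )
  class(res) <- "mb_eligibility"
  res
}

#' @export
print.mb_eligibility <- function(x, ...) {
  cat("Sedentary-pattern screen\n")
  cat(sprintf("  mean daily sedentary: %.1f h\n", x$mean_daily_sedentary_hours))
  cat(sprintf("  >50%% sedentary time in bouts > 30 min: %s\n",
              x$prolonged_criterion_met))
  cat(sprintf("  weekly MVPA: %.0f min (guideline not met: %s)\n",
              x$mvpa_week_minutes, x$guideline_not_met))
  cat(sprintf("  eligible: %s (%d valid days)\n", x$eligible, x$n_valid_days))
  invisible(x)
}
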