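#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the day-to-day statistical structure of a highly
#' sedentary stroke cohort wearing a thigh-worn posture monitor: person-level
#' baseline means drawn from a between-person distribution, Gaussian
#' day-to-day noise within person, bout-structured sedentary accumulation
#' with a long right tail (so prolonged >30-min bouts occur), and an
#' additive intervention effect switched on at each participant's allocated
#' baseline end. Defaults reproduce the screened population the analysis
#' is designed for: about 11.4 h/day of baseline sedentary time with a
#' between-person SD of 1.1 h and day-to-day SD of about 1.2 h, a
#' fragmentation index around 4 breaks per sedentary hour, a 15.5-h waking
#' window, and intervention effects of -1.3 h on sedentary time and +1.1
#' breaks/h on fragmentation.
#'
#' @param n_per_group Participants per group (groups `PS` and `NPS`).
#' @param window_hours Waking-window length (h).
#' @param sed_baseline_mean,sed_between_sd,sed_within_sd Baseline daily
#'   sedentary hours: population mean, between-person SD, within-person
#'   day-to-day SD.
#' @param frag_baseline_mean,frag_between_sd,frag_within_sd Fragmentation
#'   index (sedentary bouts per sedentary hour), same roles.
#' @param mvpa_mean,mvpa_between_sd,mvpa_within_sd Daily
#'   moderate-to-vigorous activity minutes.
#' @param effect_sedentary_hours Additive intervention effect on daily
#'   sedentary hours (negative = reduction).
#' @param effect_fragmentation Additive effect on the fragmentation index.
#' @param effect_mvpa_minutes Additive effect on daily MVPA minutes (part
#'   of what replaces the removed sedentary time; the rest becomes light
#'   activity implicitly, since the waking window is fixed).
#' @param effect_onset `"step"` (full effect from the first intervention
#'   day) or `"ramp"` (linear ramp over `ramp_weeks`).
#' @param ramp_weeks Ramp length when `effect_onset = "ramp"`.
#' @param group_effect_scale Named multipliers applied to all effects per
#'   group; `c(PS = 1, NPS = 1)` gives both groups the same effect.
#' @param bout_sdlog Log-scale SD of the lognormal sedentary bout-length
#'   distribution (larger = heavier tail, more prolonged bouts).
#' @param candidate_durations,intervention_weeks,measurement_weeks,followup_days
#'   Passed to [design_spec()].
#' @param allocation Baseline allocation mode, see [allocate_baselines()].
#' @param dropout `NULL`, or `list(group =, week =)`: one participant of
#'   that group stops measuring after that many intervention weeks (their
#'   earlier days stay in the analysis, following intention-to-treat).
#'   The default mirrors a 14-participant study in which one participant
#'   without participatory support dropped out after 5 weeks.
#' @param start_date First measurement date.
#' @param rise_time Diary rise time (HH:MM); bed time follows from
#'   `window_hours`.
#' @param seed Master seed; every random draw flows from it.
#' @return List of class `mb_synth_config`.
#' @export
synthetic_config <- function(n_per_group = 7,
                             window_hours = 15.5,
                             sed_baseline_mean = 11.4,
                             sed_between_sd = 1.1,
                             sed_within_sd = 1.2,
                             frag_baseline_mean = 4.0,
                             frag_between_sd = 1.4,
                             frag_within_sd = 0.9,
                             mvpa_mean = 15,
                             mvpa_between_sd = 5,
                             mvpa_within_sd = 6,
                             effect_sedentary_hours = -1.3,
                             effect_fragmentation = 1.1,
                             effect_mvpa_minutes = 18,
                             effect_onset = c("step", "ramp"),
                             ramp_weeks = 15,
                             group_effect_scale = c(PS = 1, NPS = 1),
                             bout_sdlog = 1,
                             candidate_durations = c(4, 6, 8, 10, 12, 14),
                             intervention_weeks = 15,
                             measurement_weeks = c(1, 8, 15),
                             followup_days = 7,
                             allocation = c("independent", "balanced"),
                             dropout = list(group = "NPS", week = 5),
                             start_date = as.Date("2021-03-01"),
                             rise_time = "07:30",
                             seed = 1) {
  cfg <- as.list(environment())
  cfg$effect_onset <- match.arg(effect_onset)
  cfg$allocation <- match.arg(allocation)
  stopifnot(window_hours > 0, window_hours <= 24,
            sed_between_sd >= 0, sed_within_sd >= 0,
            frag_between_sd >= 0, frag_within_sd >= 0)
  class(cfg) <- "mb_synth_config"
  cfg
}

# effect multiplier per measured day (step vs linear ramp over weeks)
onset_factor <- function(cfg, day, baseline_days) {
  int_day <- day - baseline_days
  out <- as.numeric(int_day > 0)
  if (cfg$effect_onset == "ramp") {
    wk <- ceiling(int_day / 7)
    out <- out * pmin(1, wk / cfg$ramp_weeks)
  }
  out
}

# Draw day-level outcome targets for a whole cohort. Shared by the fast
# metric-level simulator and the event-stream generator so both see the
# same generative model.
cohort_day_targets <- function(cfg) {
  ids <- c(sprintf("PS-%d", seq_len(cfg$n_per_group)),
           sprintf("NPS-%d", seq_len(cfg$n_per_group)))
  groups <- rep(c("PS", "NPS"), each = cfg$n_per_group)
  design <- design_spec(ids, groups,
                        candidate_durations = cfg$candidate_durations,
                        intervention_weeks = cfg$intervention_weeks,
                        followup_days = cfg$followup_days,
                        measurement_weeks = cfg$measurement_weeks,
                        seed = NULL)
  durations <- allocate_baselines(design, mode = cfg$allocation)

  dropout_id <- NULL
  if (!is.null(cfg$dropout)) {
    in_group <- ids[groups == cfg$dropout$group]
    dropout_id <- in_group[length(in_group)]
  }

  days <- lapply(seq_along(ids), function(i) {
    r <- durations[[i]]
    scale <- unname(cfg$group_effect_scale[groups[i]])
    if (is.na(scale)) scale <- 1
    sched <- measurement_schedule(r, cfg$intervention_weeks,
                                  cfg$measurement_weeks, cfg$followup_days)
    if (identical(ids[i], dropout_id)) {
      sched <- sched[sched$day <= r + cfg$dropout$week * 7, , drop = FALSE]
    }
    nd <- nrow(sched)
    p_sed <- clamp(rnorm(1, cfg$sed_baseline_mean, cfg$sed_between_sd),
                   2, cfg$window_hours - 0.5)
    p_frag <- clamp(rnorm(1, cfg$frag_baseline_mean, cfg$frag_between_sd),
                    0.5, 20)
    p_mvpa <- clamp(rnorm(1, cfg$mvpa_mean, cfg$mvpa_between_sd), 0, 120)
    f <- onset_factor(cfg, sched$day, r)
    sed <- clamp(p_sed + rnorm(nd, 0, cfg$sed_within_sd) +
                   scale * cfg$effect_sedentary_hours * f,
                 0.5, cfg$window_hours)
    frag <- clamp(p_frag + rnorm(nd, 0, cfg$frag_within_sd) +
                    scale * cfg$effect_fragmentation * f,
                  0.1, 30)
    mvpa <- clamp(p_mvpa + rnorm(nd, 0, cfg$mvpa_within_sd) +
                    scale * cfg$effect_mvpa_minutes * f,
                  0, pmax(0, (cfg$window_hours - sed) * 60 - 5))
    tibble(
      id = ids[i], group = groups[i], day = sched$day, phase = sched$phase,
      date = cfg$start_date + sched$day - 1, valid = TRUE,
      sedentary_hours = sed, fragmentation_index = frag,
      mvpa_minutes = mvpa,
      lpa_hours = cfg$window_hours - sed - mvpa / 60
    )
  })
  list(design = design, durations = durations,
       dropout_id = dropout_id, data = bind_rows(days))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a cohort at the daily-metric level
#'
#' The fast path for simulation studies (type-I error, power, parameter
#' recovery): draws day-level outcome values directly from the generative
#' model, skipping event-stream construction. [generate_cohort()] layers
#' bout-level event streams over the identical day-level targets.
#'
#' @param config A [synthetic_config()].
#' @return List with `data` (long tibble: `id`, `group`, `day`, `phase`,
#'   `date`, `valid`, outcome columns), `durations` (named vector) and
#'   `design`.
#' @export
simulate_metric_cohort <- function(config) {
  out <- with_seed(config$seed, cohort_day_targets(config))
  out[c("data", "durations", "design", "dropout_id")]
}

#' Generate one waking day of posture events
#'
#' Builds an alternating sedentary-bout / upright-gap event sequence that
#' tiles the waking window exactly and realizes the requested daily
#' targets: total sedentary time is matched exactly (bout lengths are drawn
#' lognormal, then rescaled), the bout count approximates
#' `fragmentation_index * sedentary_hours`, stepping at `mvpa_cadence + 15`
#' steps/min fills the MVPA allotment, and the remaining upright time is
#' standing plus slow stepping (light activity). Uses the current RNG
#' state; seed upstream for reproducibility.
#'
#' @param sedentary_hours Target daily sedentary time (h).
#' @param fragmentation_index Target bouts per sedentary hour.
#' @param mvpa_minutes Target stepping minutes at or above the MVPA
#'   cadence.
#' @param window_hours Waking-window length (h).
#' @param start Window start (POSIXct).
#' @param mvpa_cadence Cadence threshold used downstream to classify MVPA.
#' @param bout_sdlog Lognormal log-SD of bout lengths.
#' @return Event tibble in the format of [read_events()].
#' @export
generate_day <- function(sedentary_hours, fragmentation_index, mvpa_minutes,
                         window_hours,
                         start = as.POSIXct("2021-03-01 07:30:00", tz = "UTC"),
                         mvpa_cadence = 100, bout_sdlog = 1) {
  window_s <- window_hours * 3600
  sed_s <- sedentary_hours * 3600
  mvpa_s <- mvpa_minutes * 60
  if (sed_s > window_s + 1e-6) {
    abort("infeasible targets: sedentary time exceeds the waking window")
  }
  upright_s <- window_s - sed_s
  if (mvpa_s > upright_s + 1e-6) {
    abort("infeasible targets: MVPA does not fit in the upright time")
  }
  if (upright_s <= 1e-6) {
    return(tibble(start = start, duration = window_s,
                  activity = activity_factor("sedentary"), cadence = 0))
  }

  n_bouts <- max(1L, as.integer(round(fragmentation_index * sedentary_hours)))
  # each upright gap needs a sliver of time; cap the bout count accordingly
  n_bouts <- min(n_bouts, max(1L, as.integer(floor(upright_s / 30))))
  bouts <- rlnorm(n_bouts, log(sed_s / n_bouts) - bout_sdlog^2 / 2, bout_sdlog)
  bouts <- bouts * sed_s / sum(bouts)
  gaps <- rlnorm(n_bouts, log(upright_s / n_bouts) - 0.125, 0.5)
  gaps <- gaps * upright_s / sum(gaps)

  rows <- vector("list", n_bouts * 2L)
  for (k in seq_len(n_bouts)) {
    rows[[2 * k - 1]] <- tibble(duration = bouts[k], activity = "sedentary",
                                cadence = 0)
    rows[[2 * k]] <- split_gap(gaps[k], gaps[k] * mvpa_s / upright_s,
                               mvpa_cadence)
  }
  ev <- bind_rows(rows)
  ev$start <- start + c(0, cumsum(ev$duration))[seq_len(nrow(ev))]
  tibble(start = ev$start, duration = ev$duration,
         activity = activity_factor(ev$activity), cadence = ev$cadence)
}

# one upright gap = standing + light stepping + (optionally) brisk stepping;
# sub-second slivers are folded into the largest part so the gap is tiled
# exactly
split_gap <- function(gap_s, step_s, mvpa_cadence) {
  step_s <- min(step_s, gap_s)
  rest <- gap_s - step_s
  light <- rest * runif(1, 0.15, 0.35)
  dur <- c(rest - light, light, step_s)
  act <- c("standing", "stepping", "stepping")
  cad <- c(0, runif(1, 50, 85), mvpa_cadence + 15)
  keep <- dur > 0.5
  keep[which.max(dur)] <- TRUE
  if (any(!keep)) {
    dur[which.max(dur)] <- dur[which.max(dur)] + sum(dur[!keep])
  }
  tibble(duration = dur[keep], activity = act[keep], cadence = cad[keep])
}

#' Generate a synthetic multiple-baseline cohort as event streams
#'
#' Materializes the full measurement artifacts of a staggered-start study:
#' per-participant posture-event streams (built day by day with
#' [generate_day()] from the same day-level targets as
#' [simulate_metric_cohort()]), a wake/sleep diary, and the design record.
#' Optionally writes them to disk in the exact CSV dialects that
#' [read_events()] and [read_diary()] parse, plus a design YAML.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory; created if needed.
#' @return List with `design`, `durations`, `day_targets` (tibble),
#'   `events` (named list of event tibbles), `diary` (tibble) and, when
#'   written, `files`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  out <- with_seed(config$seed, {
    targ <- cohort_day_targets(config)
    rise_s <- parse_clock(config$rise_time)
    events <- lapply(split(targ$data, targ$data$id), function(d) {
      d <- d[order(d$day), ]
      bind_rows(lapply(seq_len(nrow(d)), function(k) {
        day_start <- as.POSIXct(paste(d$date[k]), tz = "UTC") + rise_s
        generate_day(d$sedentary_hours[k], d$fragmentation_index[k],
                     d$mvpa_minutes[k], config$window_hours,
                     start = day_start, bout_sdlog = config$bout_sdlog)
      }))
    })
    bed_s <- rise_s + config$window_hours * 3600
    bed_str <- sprintf("%02d:%02d", (bed_s %/% 3600) %% 24,
                       round((bed_s %% 3600) / 60))
    diary <- dplyr::distinct(tibble(
      participant_id = targ$data$id, date = targ$data$date,
      rise_time = config$rise_time, bed_time = bed_str
    ))
    list(design = targ$design, durations = targ$durations,
         dropout_id = targ$dropout_id, day_targets = targ$data,
         events = events, diary = diary)
  })

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    for (pid in names(out$events)) {
      f <- file.path(dir, paste0(pid, "_events.csv"))
      write_events(out$events[[pid]], f, dialect = "activpal_events")
      files[pid] <- f
    }
    readr::write_csv(
      dplyr::mutate(out$diary, date = as.character(.data$date)),
      file.path(dir, "diary.csv"), progress = FALSE
    )
    yaml::write_yaml(list(
      participants = out$design$participants,
      group = out$design$group,
      candidate_durations = out$design$candidate_durations,
      baseline_days = as.list(out$durations),
      intervention_weeks = out$design$intervention_weeks,
      measurement_weeks = out$design$measurement_weeks,
      followup_days = out$design$followup_days,
      seed = config$seed
    ), file.path(dir, "design.yaml"))
    out$files <- c(files, diary = file.path(dir, "diary.csv"),
                   design = file.path(dir, "design.yaml"))
  }
  out
}
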