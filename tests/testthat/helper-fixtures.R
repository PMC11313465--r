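# Fixture builders and independent oracle implementations. Oracles are
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate correctness.

`%||%` <- function(a, b) if (is.null(a)) b else a

t0 <- function(clock = "07:30:00", date = "2021-03-01") {
  as.POSIXct(paste(date, clock), tz = "UTC")
}

# Build a gapless event sequence from parallel vectors (durations in
# seconds); gaps can be introduced by inserting a "gap" activity, which is
# dropped after start times are laid out.
make_events <- function(durations, activities, cadences = NULL,
                        start = t0()) {
  cadences <- cadences %||% rep(0, length(durations))
  starts <- start + c(0, cumsum(durations))[seq_along(durations)]
  ev <- tibble::tibble(
    start = starts, duration = durations,
    activity = activities, cadence = cadences
  )
  ev <- ev[ev$activity != "gap", , drop = FALSE]
  ev$activity <- factor(ev$activity,
                        levels = c("sedentary", "standing", "stepping"))
  ev
}

wrap_day <- function(events, window_hours = NULL) {
  window_hours <- window_hours %||% (sum(events$duration) / 3600)
  list(events = list(events), window_hours = window_hours,
       wear_hours = sum(events$duration) / 3600)
}

# naive bout oracle: walk events in order, merging contiguous sedentary time
oracle_bouts <- function(events) {
  bouts <- list()
  cur <- NULL
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (as.character(e$activity) == "sedentary") {
      if (!is.null(cur) &&
          abs(as.numeric(e$start) - cur$end) <= 1e-6) {
        cur$end <- as.numeric(e$start) + e$duration
      } else {
        if (!is.null(cur)) bouts[[length(bouts) + 1]] <- cur
        cur <- list(start = as.numeric(e$start),
                    end = as.numeric(e$start) + e$duration)
      }
    } else {
      if (!is.null(cur)) bouts[[length(bouts) + 1]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) bouts[[length(bouts) + 1]] <- cur
  if (length(bouts) == 0) {
    return(data.frame(start = numeric(), duration = numeric()))
  }
  data.frame(
    start = vapply(bouts, `[[`, numeric(1), "start"),
    duration = vapply(bouts, function(b) b$end - b$start, numeric(1))
  )
}

# brute-force PEM: count post days strictly better than the baseline median
oracle_pem <- function(baseline, post, direction) {
  med <- stats::median(baseline)
  n_better <- 0
  for (v in post) {
    better <- if (direction == "lower_is_better") v < med else v > med
    if (better) n_better <- n_better + 1
  }
  100 * n_better / length(post)
}

# a minimal participant series for effect-size / randomization tests
make_series <- function(values, phases, days = seq_along(values),
                        valid = TRUE, id = "p1", group = "PS",
                        outcome = "y") {
  s <- tibble::tibble(id = id, group = group, day = days, phase = phases,
                      valid = rep_len(valid, length(values)))
  s[[outcome]] <- values
  s
}

# two-participant cohort with an unmistakable step change at the true starts
make_step_cohort <- function(durations, step = -10, n_days = 12,
                             noise = 0, seed = 1) {
  set.seed(seed)
  data <- dplyr::bind_rows(lapply(names(durations), function(pid) {
    r <- durations[[pid]]
    v <- ifelse(seq_len(n_days) > r, step, 0) + rnorm(n_days, 0, noise)
    make_series(v, phases = ifelse(seq_len(n_days) <= r, "A", "B"), id = pid)
  }))
  data
}

write_csv_text <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
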