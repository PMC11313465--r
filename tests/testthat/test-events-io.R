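test_that("activpal-dialect event files parse into ordered classed events", {
  f <- write_csv_text(c(
    "Time,Interval,ActivityCode,CumulativeStepCount",
    "2021-03-01 08:00:00,3600,0,0",
    "2021-03-01 09:00:00,600,1,0",
    "2021-03-01 09:10:00,300,2,550"
  ))
  ev <- read_events(f, dialect = "activpal_events")
  expect_equal(nrow(ev), 3)
  expect_equal(as.character(ev$activity), c("sedentary", "standing", "stepping"))
  expect_equal(ev$duration, c(3600, 600, 300))
  # 550 steps over 5 min of stepping
  expect_equal(ev$cadence, c(0, 0, 110))

  # Excel serial timestamps resolve to the same clock times
  serial <- 44256 + 8 / 24  # 2021-03-01 08:00
  f2 <- write_csv_text(c(
    "Time,Interval,ActivityCode,CumulativeStepCount",
    sprintf("%.10f,3600,0,0", serial)
  ))
  ev2 <- read_events(f2, dialect = "activpal_events")
  expect_equal(format(ev2$start, "%H:%M:%S"), "08:00:00")
})

test_that("an empty event file with a header yields an empty event table", {
  f <- write_csv_text("Time,Interval,ActivityCode,CumulativeStepCount")
  ev <- read_events(f, dialect = "activpal_events")
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("start", "duration", "activity", "cadence"))
})

test_that("missing columns and bad rows produce informative format errors", {
  f <- write_csv_text(c("Time,Interval,ActivityCode", "2021-03-01 08:00:00,60,0"))
  expect_error(read_events(f, dialect = "activpal_events"),
               "CumulativeStepCount")
  f2 <- write_csv_text(c(
    "Time,Interval,ActivityCode,CumulativeStepCount",
    "2021-03-01 08:00:00,60,0,0",
    "not-a-time,60,0,0"
  ))
  expect_error(read_events(f2, dialect = "activpal_events"), "row 2")
  f3 <- write_csv_text(c(
    "Time,Interval,ActivityCode,CumulativeStepCount",
    "2021-03-01 08:00:00,60,9,0"
  ))
  expect_error(read_events(f3, dialect = "activpal_events"), "activity code")
  # ... unless a class map translates the unknown code
  ev <- read_events(f3, dialect = "activpal_events",
                    class_map = c(`9` = "standing"))
  expect_equal(as.character(ev$activity), "standing")
})

test_that("an event overlapping its successor is truncated with a warning", {
  f <- write_csv_text(c(
    "Time,Interval,ActivityCode,CumulativeStepCount",
    "2021-03-01 08:00:00,600,0,0",
    "2021-03-01 08:09:00,300,1,0"  # starts 60 s before the first ends
  ))
  expect_warning(ev <- read_events(f, dialect = "activpal_events"),
                 "truncated")
  expect_equal(ev$duration, c(540, 300))
})

test_that("plain-dialect round trip preserves start, duration and class", {
  set.seed(7)
  d <- generate_day(8, 3, 20, 15)
  f <- tempfile(fileext = ".csv")
  write_events(d, f, dialect = "plain")
  d2 <- read_events(f, dialect = "plain")
  expect_equal(as.numeric(d2$start), as.numeric(d$start), tolerance = 1e-9)
  expect_equal(d2$duration, d$duration)
  expect_identical(d2$activity, d$activity)
  # the activpal dialect round-trips classes and durations too
  f3 <- tempfile(fileext = ".csv")
  write_events(d, f3, dialect = "activpal_events")
  d3 <- read_events(f3, dialect = "activpal_events")
  expect_identical(d3$activity, d$activity)
  expect_equal(d3$duration, d$duration)
})

test_that("diaries parse windows, including bed times past midnight", {
  f <- write_csv_text(c(
    "participant_id,date,rise_time,bed_time",
    "p1,2021-03-01,07:30,23:00",
    "p1,2021-03-02,08:00,00:30"
  ))
  d <- read_diary(f)
  expect_equal(d$window_hours, c(15.5, 16.5))

  fdup <- write_csv_text(c(
    "participant_id,date,rise_time,bed_time",
    "p1,2021-03-01,07:30,23:00",
    "p1,2021-03-01,08:00,22:00"
  ))
  expect_error(read_diary(fdup), "duplicate")
})

test_that("waking-day split clips boundary-spanning events and conserves time", {
  # sedentary 22:00-24:00 against a 23:00 bed time keeps exactly 1 h
  ev <- make_events(c(2 * 3600), c("sedentary"), start = t0("22:00:00"))
  diary <- read_diary(write_csv_text(c(
    "participant_id,date,rise_time,bed_time",
    "p1,2021-03-01,07:30,23:00"
  )))
  wd <- split_waking_days(ev, diary)
  expect_equal(wd$wear_hours, 1)
  expect_equal(wd$events[[1]]$duration, 3600)
  expect_equal(as.character(wd$events[[1]]$activity), "sedentary")

  # events fully inside the window are untouched
  ev2 <- make_events(c(3600, 1800, 600), c("sedentary", "standing", "stepping"),
                     c(0, 0, 105), start = t0("09:00:00"))
  wd2 <- split_waking_days(ev2, diary)
  expect_equal(sum(wd2$events[[1]]$duration), sum(ev2$duration))

  # no day contains an event outside its window
  for (i in seq_len(nrow(wd2))) {
    e <- wd2$events[[i]]
    expect_true(all(e$start >= wd2$window_start[i]))
    expect_true(all(e$start + e$duration <= wd2$window_end[i] + 1e-6))
  }
})

test_that("clipping conserves in-window time across multi-day recordings", {
  set.seed(21)
  cfg <- synthetic_config(n_per_group = 1, dropout = NULL, seed = 5)
  g <- generate_cohort(cfg)
  ev <- g$events[[1]]
  diary <- g$diary[g$diary$participant_id == names(g$events)[1], ]
  wd <- split_waking_days(ev, diary)
  # windows tile the measured days, so total event time is conserved
  expect_equal(sum(vapply(wd$events, function(e) sum(e$duration), numeric(1))),
               sum(ev$duration), tolerance = 1e-8)
})

test_that("dates without a diary entry are dropped, or recovered by fallback", {
  # two days of events, diary only covers the first
  day1 <- make_events(c(3600, 1800), c("sedentary", "standing"),
                      start = t0("08:00:00"))
  night <- make_events(7 * 3600, "sedentary", start = t0("23:30:00"))
  day2 <- make_events(c(1800, 3600), c("standing", "sedentary"),
                      start = t0("08:00:00", "2021-03-02"))
  ev <- dplyr::bind_rows(day1, night, day2)
  diary <- read_diary(write_csv_text(c(
    "participant_id,date,rise_time,bed_time",
    "p1,2021-03-01,07:30,23:30"
  )))
  expect_warning(wd <- split_waking_days(ev, diary), "no diary entry")
  expect_equal(nrow(wd), 1)

  suppressWarnings(expect_message(
    wd2 <- split_waking_days(ev, diary, fallback = TRUE), "fallback"))
  # the overnight sedentary event ends 06:30, which becomes day 2's rise
  d2 <- wd2[wd2$date == as.Date("2021-03-02"), ]
  expect_equal(format(d2$window_start, "%H:%M"), "06:30")

  expect_error(split_waking_days(ev, diary[0, ], fallback = FALSE),
               "uncovered")
})
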