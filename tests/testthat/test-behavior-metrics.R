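test_that("contiguous sedentary events merge into bouts; interruptions split them", {
  ev <- make_events(
    c(20, 15, 2, 40) * 60,
    c("sedentary", "sedentary", "standing", "sedentary")
  )
  b <- sedentary_bouts(ev)
  expect_equal(b$duration, c(35, 40) * 60)

  expect_equal(nrow(sedentary_bouts(make_events(600, "standing"))), 0)

  one <- make_events(15.5 * 3600, "sedentary")
  expect_equal(sedentary_bouts(one)$duration, 15.5 * 3600)

  # an in-window gap terminates a bout even with no interposed event
  gapped <- make_events(c(1800, 600, 1800), c("sedentary", "gap", "sedentary"))
  expect_equal(nrow(sedentary_bouts(gapped)), 2)
})

test_that("bout detection matches the naive oracle on random days", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:25, 1)
    ev <- make_events(
      durations = runif(n, 30, 5000),
      activities = sample(c("sedentary", "standing", "stepping", "gap"), n,
                          replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1)),
      cadences = runif(n, 0, 130)
    )
    got <- sedentary_bouts(ev)
    want <- oracle_bouts(ev)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$duration, want$duration, tolerance = 1e-9)
  }
})

test_that("daily metrics follow their definitions on a constructed day", {
  # 10 h sedentary in 10 equal bouts -> fragmentation index exactly 1
  parts <- rep(c(3600, 600), 10)
  acts <- rep(c("sedentary", "standing"), 10)
  day <- wrap_day(make_events(parts, acts))
  m <- day_metrics(day)
  expect_equal(m$sedentary_hours, 10)
  expect_equal(m$fragmentation_index, 1)

  # one 4-h bout + four 30.01-min bouts, 2 h standing, 30 min brisk stepping
  sb <- 30.01 * 60
  ev <- make_events(
    c(4 * 3600, 24 * 60, sb, 24 * 60, sb, 24 * 60, sb, 24 * 60, sb,
      2 * 3600 - 4 * 24 * 60, 30 * 60),
    c("sedentary", "standing", "sedentary", "standing", "sedentary",
      "standing", "sedentary", "standing", "sedentary", "standing",
      "stepping"),
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 120)
  )
  day2 <- wrap_day(ev)
  m2 <- day_metrics(day2, min_wear_hours = 8)
  sed_h <- 4 + 4 * sb / 3600
  expect_equal(m2$sedentary_hours, sed_h)
  expect_equal(m2$fragmentation_index, 5 / sed_h)
  expect_equal(m2$prolonged_bout_fraction, 1)  # every bout exceeds 30 min
  expect_equal(m2$lpa_hours, 2)
  expect_equal(m2$mvpa_minutes, 30)
  expect_true(m2$valid)

  # a 30.00-min bout is NOT prolonged under the strict > 30 min rule
  ev3 <- make_events(c(30 * 60, 600), c("sedentary", "standing"))
  expect_equal(day_metrics(wrap_day(ev3), min_wear_hours = 0)$prolonged_bout_fraction, 0)
})

test_that("on gapless days the behaviors partition wear time exactly", {
  set.seed(11)
  for (rep in 1:20) {
    d <- generate_day(
      sedentary_hours = runif(1, 6, 12), fragmentation_index = runif(1, 1, 8),
      mvpa_minutes = runif(1, 0, 40), window_hours = 15.5
    )
    m <- day_metrics(wrap_day(d, 15.5))
    expect_equal(m$sedentary_hours + m$lpa_hours + m$mvpa_minutes / 60, 15.5,
                 tolerance = 1e-9)
  }
})

test_that("fragmentation is invariant to splitting a bout into contiguous events", {
  ev <- make_events(c(3600, 600, 5400), c("sedentary", "standing", "sedentary"))
  m1 <- day_metrics(wrap_day(ev), min_wear_hours = 0)
  # split the 90-min event into three back-to-back sedentary events
  ev2 <- make_events(c(3600, 600, 1800, 1800, 1800),
                     c("sedentary", "standing", rep("sedentary", 3)))
  m2 <- day_metrics(wrap_day(ev2), min_wear_hours = 0)
  expect_equal(m2$fragmentation_index, m1$fragmentation_index)
  expect_equal(m2$sedentary_hours, m1$sedentary_hours)
})

test_that("removing a bout-terminating interruption never raises fragmentation", {
  set.seed(3)
  for (rep in 1:20) {
    n_pairs <- sample(3:8, 1)
    ev <- make_events(runif(2 * n_pairs, 300, 3600),
                      rep(c("sedentary", "standing"), n_pairs))
    m_before <- day_metrics(wrap_day(ev), min_wear_hours = 0)
    # turn one interruption that separates two bouts back into sitting
    interior <- seq(2, 2 * n_pairs - 2, by = 2)
    gap_idx <- interior[sample(length(interior), 1)]
    ev$activity[gap_idx] <- factor("sedentary", levels = levels(ev$activity))
    m_after <- day_metrics(wrap_day(ev), min_wear_hours = 0)
    expect_lte(m_after$fragmentation_index, m_before$fragmentation_index + 1e-9)
  }
})

test_that("the sedentary-pattern screen applies both eligibility branches", {
  week <- function(sed, prolonged, mvpa_day) {
    tibble::tibble(sedentary_hours = rep(sed, 7),
                   prolonged_bout_fraction = rep(prolonged, 7),
                   mvpa_minutes = rep(mvpa_day, 7), valid = TRUE)
  }
  # 10 h sedentary, 60% in long bouts: eligible despite 200 MVPA min/week
  r1 <- screen_eligibility(week(10, 0.6, 200 / 7))
  expect_true(r1$eligible)
  expect_true(r1$prolonged_criterion_met)
  expect_false(r1$guideline_not_met)

  # below the 9.5 h floor nothing else matters
  r2 <- screen_eligibility(week(8, 0.9, 0))
  expect_false(r2$eligible)

  # 10 h but neither sub-criterion: 40% long bouts and 160 MVPA min/week
  r3 <- screen_eligibility(week(10, 0.4, 160 / 7))
  expect_false(r3$eligible)

  # guideline branch: 10 h, 40% long bouts, only 100 MVPA min/week
  r4 <- screen_eligibility(week(10, 0.4, 100 / 7))
  expect_true(r4$eligible)

  # too few valid days is an error naming the count
  short <- week(10, 0.6, 10)[1:3, ]
  expect_error(screen_eligibility(short), "3 valid")
})

test_that("weekly MVPA is rescaled to 7 days when fewer days are valid", {
  m <- tibble::tibble(sedentary_hours = rep(10, 5),
                      prolonged_bout_fraction = 0.6,
                      mvpa_minutes = rep(10, 5), valid = TRUE)
  r <- screen_eligibility(m, min_valid_days = 4)
  expect_equal(r$mvpa_week_minutes, 50 * 7 / 5)
})
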