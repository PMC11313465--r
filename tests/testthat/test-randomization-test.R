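test_that("participant effects are post-minus-pre means over valid days", {
  s <- make_series(c(12, 12, 10, 10), phases = c("A", "A", "B", "B"))
  expect_equal(participant_effect(s, "y", 2), -2)

  s2 <- make_series(rep(5, 8), phases = c(rep("A", 4), rep("B", 4)))
  for (d in 1:7) expect_equal(participant_effect(s2, "y", d), 0)

  s3 <- make_series(c(11.8, 12.2, 12.0, 10.4, 10.8),
                    phases = c("A", "A", "A", "B", "B"))
  expect_equal(participant_effect(s3, "y", 3), -1.4)

  expect_error(participant_effect(s3, "y", 5), "post")
  expect_error(participant_effect(s3, "y", 0), "baseline")

  # invalid days are excluded from both sides
  s4 <- make_series(c(12, 100, 12, 10), phases = c("A", "A", "A", "B"),
                    valid = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(participant_effect(s4, "y", 3), -2)
})

test_that("all-constant data yield p = 1 under any design", {
  durs <- setNames(c(4, 6, 8), c("a", "b", "c"))
  data <- dplyr::bind_rows(lapply(names(durs), function(pid) {
    make_series(rep(3, 12), phases = rep(c("A", "B"), each = 6), id = pid)
  }))
  r <- group_test(data, "y", durs)
  expect_equal(r$p_two_tailed, 1)
  expect_equal(r$statistic_observed, 0)
})

test_that("a two-participant design with a clean step change gives p = 1/2", {
  durs <- setNames(c(4, 6), c("a", "b"))
  data <- make_step_cohort(durs, step = -10, noise = 0.01)
  r <- group_test(data, "y", durs)
  expect_equal(r$mode, "exact")
  expect_equal(r$n_assignments, 2)
  expect_equal(r$p_two_tailed, 0.5)
  # hand enumeration: identity assignment is strictly more extreme than swap
  E_swap <- mean(c(participant_effect(data[data$id == "a", ], "y", 6),
                   participant_effect(data[data$id == "b", ], "y", 4)))
  expect_lt(abs(E_swap), abs(r$statistic_observed))
})

test_that("a strong staggered step change across six participants attains the minimal p", {
  durs <- setNames(c(4, 6, 8, 10, 12, 14), sprintf("p%d", 1:6))
  data <- make_step_cohort(durs, step = -10, n_days = 20, noise = 1, seed = 2)
  r <- group_test(data, "y", durs)
  expect_equal(r$p_two_tailed, 1 / 720)
  expect_lt(r$p_two_tailed, 0.01)
})

test_that("the smallest attainable p is one over the assignment count", {
  expect_equal(min_attainable_p(setNames(c(4, 6, 8, 10, 12, 14),
                                         sprintf("p%d", 1:6))), 1 / 720)
  expect_equal(min_attainable_p(setNames(c(4, 6), c("a", "b"))), 0.5)
  expect_equal(min_attainable_p(setNames(c(4, 4, 6, 8, 10, 12, 14),
                                         sprintf("p%d", 1:7))), 1 / 2520)
})

test_that("negating every outcome leaves the two-tailed p unchanged", {
  set.seed(5)
  cfg <- synthetic_config(n_per_group = 3, allocation = "balanced",
                          dropout = NULL, seed = 31)
  sim <- simulate_metric_cohort(cfg)
  r1 <- group_test(sim$data, "sedentary_hours", sim$durations)
  neg <- sim$data
  neg$sedentary_hours <- -neg$sedentary_hours
  r2 <- group_test(neg, "sedentary_hours", sim$durations)
  expect_equal(r2$p_two_tailed, r1$p_two_tailed)
  expect_equal(r2$statistic_observed, -r1$statistic_observed)
})

test_that("exact and Monte Carlo p agree on a mid-size fixture", {
  cfg <- synthetic_config(n_per_group = 3, allocation = "balanced",
                          effect_sedentary_hours = -0.8, dropout = NULL,
                          seed = 17)
  sim <- simulate_metric_cohort(cfg)
  ex <- group_test(sim$data, "sedentary_hours", sim$durations, mode = "exact")
  mc <- group_test(sim$data, "sedentary_hours", sim$durations,
                   mode = "monte_carlo", n_mc = 20000, seed = 4)
  se <- sqrt(ex$p_two_tailed * (1 - ex$p_two_tailed) / 20000)
  expect_lt(abs(mc$p_two_tailed - ex$p_two_tailed), 3 * se + 1e-4)
})

test_that("subgroup tests only permute within the subgroup", {
  cfg <- synthetic_config(n_per_group = 3, allocation = "balanced",
                          dropout = NULL, seed = 23)
  sim <- simulate_metric_cohort(cfg)
  ps_ids <- grep("^PS", names(sim$durations), value = TRUE)
  r <- group_test(sim$data[sim$data$id %in% ps_ids, ], "sedentary_hours",
                  sim$durations[ps_ids])
  expect_equal(r$space_count, multiset_permutations(sim$durations[ps_ids]) |> nrow())
  expect_lte(r$n_assignments, 6)  # 3 participants, at most 3! assignments
})

test_that("stratified permutation keeps durations within their group", {
  durs <- setNames(c(4, 6, 8, 10), c("a", "b", "c", "d"))
  strata <- setNames(c("g1", "g1", "g2", "g2"), names(durs))
  data <- make_step_cohort(durs, step = -5, n_days = 14, noise = 0.1, seed = 9)
  r <- group_test(data, "y", durs, strata = strata)
  expect_equal(r$n_assignments, 4)  # 2! x 2!
  expect_equal(min_attainable_p(durs, strata = strata), 0.25)
})

test_that("a degenerate single-assignment space warns and returns p = 1", {
  durs <- setNames(c(6, 6), c("a", "b"))
  data <- make_step_cohort(durs, step = -3, noise = 0.01, seed = 3)
  expect_warning(r <- group_test(data, "y", durs), "degenerate")
  expect_equal(r$p_two_tailed, 1)
})
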