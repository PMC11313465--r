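#' Classify a PEM value
#'
#' Percentage-exceeding-the-median effect sizes are conventionally binned
#' as: >90 high, 70-90 moderate, 60-70 mild, 50-60 questionable, <50 no
#' effect. Interval notation is ambiguous at the boundaries; here a
#' boundary value goes to the higher-named bin (exactly 90 and 70 are
#' moderate, exactly 60 is mild, exactly 50 is questionable). The
#' boundaries are exposed so that the opposite convention can be selected.
#'
#' @param pem PEM value(s) in percent, in \[0, 100\].
#' @param boundaries Lower edges of the high/moderate/mild/questionable
#'   bins.
#' @return Factor with levels `high`, `moderate`, `mild`, `questionable`,
#'   `none`.
#' @export
#' @examples
#' classify_pem(c(100, 87, 60.8, 46.5))
classify_pem <- function(pem, boundaries = c(high = 90, moderate = 70,
                                             mild = 60, questionable = 50)) {
  if (any(pem < 0 | pem > 100)) {
    abort("PEM must lie in [0, 100]")
  }
  out <- ifelse(pem > boundaries[["high"]], "high",
         ifelse(pem >= boundaries[["moderate"]], "moderate",
         ifelse(pem >= boundaries[["mild"]], "mild",
         ifelse(pem >= boundaries[["questionable"]], "questionable", "none"))))
  factor(out, levels = c("high", "moderate", "mild", "questionable", "none"))
}

#' Percentage exceeding the median (PEM) for one participant
#'
#' PEM is the share of valid intervention-and-after days on which the
#' outcome was strictly better than the participant's own baseline median
#' ("better" according to `direction`). A day exactly equal to the median
#' does not count as an improvement -- with discrete or heavily tied data
#' this strictness materially changes the value, so it is worth stating.
#' Medians over an even number of baseline days use the usual midpoint
#' convention. Phase summaries use the sample standard deviation (n - 1)
#' and the difference is improvement-signed: positive = improved.
#'
#' @param series One participant's measured days: columns `day`, `phase`
#'   (`A`/`B`/`Ap`), `valid`, and the outcome.
#' @param outcome Outcome column name.
#' @param direction `"lower_is_better"` (e.g. sedentary hours) or
#'   `"higher_is_better"` (e.g. the fragmentation index).
#' @param post_phases Phases counted as "during and after the
#'   intervention"; default both B and A'.
#' @return One-row tibble: `outcome_name`, `direction`, `baseline_median`,
#'   `n_post_days`, `pem`, `category`, `mean_A`, `sd_A`, `mean_post`,
#'   `sd_post`, `difference`.
#' @export
pem <- function(series, outcome,
                direction = c("lower_is_better", "higher_is_better"),
                post_phases = c("B", "Ap")) {
  direction <- match.arg(direction)
  v <- series[[outcome]]
  base <- v[series$phase == "A" & series$valid]
  post <- v[series$phase %in% post_phases & series$valid]
  if (length(base) == 0) {
    abort("no valid baseline (phase A) days")
  }
  if (length(post) == 0) {
    abort("no valid post (phase B/A') days")
  }
  med <- median(base)
  improved <- if (direction == "lower_is_better") post < med else post > med
  pem_pct <- 100 * sum(improved) / length(post)
  mean_a <- mean(base)
  mean_post <- mean(post)
  difference <- if (direction == "lower_is_better") {
    mean_a - mean_post
  } else {
    mean_post - mean_a
  }
  tibble(
    outcome_name = outcome,
    direction = direction,
    baseline_median = med,
    n_post_days = length(post),
    pem = pem_pct,
    category = classify_pem(pem_pct),
    mean_A = mean_a,
    sd_A = if (length(base) > 1) sd(base) else NA_real_,
    mean_post = mean_post,
    sd_post = if (length(post) > 1) sd(post) else NA_real_,
    difference = difference
  )
}

#' PEM for every participant and outcome in a cohort
#'
#' @param data Long tibble of measured days: `id`, `group`, `day`, `phase`,
#'   `valid`, and the outcome columns.
#' @param outcomes Named character vector mapping outcome column names to
#'   their improvement direction, e.g.
#'   `c(sedentary_hours = "lower_is_better", fragmentation_index = "higher_is_better")`.
#' @inheritParams pem
#' @return Tibble with one row per participant x outcome, including `id`
#'   and `group`.
#' @export
cohort_pem <- function(data,
                       outcomes = c(sedentary_hours = "lower_is_better",
                                    fragmentation_index = "higher_is_better"),
                       post_phases = c("B", "Ap")) {
  ids <- unique(data$id)
  rows <- lapply(ids, function(pid) {
    s <- data[data$id == pid, , drop = FALSE]
    grp <- s$group[1]
    bind_rows(lapply(names(outcomes), function(oc) {
      r <- pem(s, oc, outcomes[[oc]], post_phases)
      dplyr::bind_cols(tibble(id = pid, group = grp), r)
    }))
  })
  bind_rows(rows)
}

#' Roll up individual PEM results into improvement counts
#'
#' A participant "improved" on an outcome when their PEM exceeds
#' `threshold` (default 60, the lower edge of a mild effect). The rollup
#' counts, overall and per group, how many participants improved on at
#' least one outcome and on both, and summarises the improvement-signed
#' differences among improvers per outcome (mean, SD, range, and counts
#' above `change_thresholds`).
#'
#' @param results PEM tibble from [cohort_pem()] (or any tibble with
#'   columns `id`, `group`, `outcome_name`, `pem`, `difference`), with
#'   exactly two outcomes per participant.
#' @param threshold PEM improvement cutoff in percent.
#' @param change_thresholds Improvement-difference cutoffs reported as
#'   exceedance counts (default 0.5 and 1, i.e. 30 and 60 min for an
#'   outcome measured in hours).
#' @return List of class `mb_rollup`: `counts` (tibble over scopes `all`
#'   and each group: n, improved on at least one / both) and `improvers`
#'   (per-outcome summary of differences among improvers).
#' @export
improvement_rollup <- function(results, threshold = 60,
                               change_thresholds = c(0.5, 1)) {
  outcomes <- unique(results$outcome_name)
  if (length(outcomes) != 2) {
    abort("improvement_rollup expects exactly two outcomes")
  }
  per_id <- lapply(split(results, results$id), function(r) {
    if (!setequal(r$outcome_name, outcomes)) {
      abort(sprintf("participant %s is missing an outcome", r$id[1]))
    }
    tibble(id = r$id[1], group = r$group[1],
           n_improved = sum(r$pem > threshold))
  })
  per_id <- bind_rows(per_id)

  count_scope <- function(d, scope) {
    tibble(scope = scope, n = nrow(d),
           at_least_one = sum(d$n_improved >= 1),
           both = sum(d$n_improved == 2))
  }
  counts <- bind_rows(
    count_scope(per_id, "all"),
    bind_rows(lapply(sort(unique(per_id$group)), function(g) {
      count_scope(per_id[per_id$group == g, ], g)
    }))
  )

  improvers <- bind_rows(lapply(outcomes, function(oc) {
    d <- results[results$outcome_name == oc & results$pem > threshold, ]
    row <- tibble(
      outcome_name = oc, n_improvers = nrow(d),
      mean_change = mean(d$difference), sd_change = sd(d$difference),
      min_change = if (nrow(d)) min(d$difference) else NA_real_,
      max_change = if (nrow(d)) max(d$difference) else NA_real_
    )
    for (ct in change_thresholds) {
      row[[sprintf("n_over_%g", ct)]] <- sum(d$difference > ct)
    }
    row
  }))

  structure(list(counts = counts, improvers = improvers,
                 threshold = threshold), class = "mb_rollup")
}

#' @export
print.mb_rollup <- function(x, ...) {
  cat(sprintf("Improvement rollup (PEM > %g%%)\n", x$threshold))
  print(as.data.frame(x$counts), row.names = FALSE)
  cat("Differences among improvers:\n")
  print(as.data.frame(x$improvers), row.names = FALSE)
  invisible(x)
}

#' Report-style PEM table
#'
#' Formats a [cohort_pem()] result the way single-case study reports print
#' it: one row per participant x outcome with PEM, phase means (SD) and
#' the improvement-signed difference, all rounded to one decimal with
#' halves away from zero.
#'
#' @param results PEM tibble from [cohort_pem()].
#' @return Tibble of formatted strings plus the effect `category`.
#' @export
pem_table <- function(results) {
  tibble(
    group = results$group,
    id = results$id,
    outcome = results$outcome_name,
    pem = sprintf("%.1f%%", round_half_up(results$pem, 1)),
    phase_A = sprintf("%.1f (%.1f)", round_half_up(results$mean_A, 1),
                      round_half_up(results$sd_A, 1)),
    phase_post = sprintf("%.1f (%.1f)", round_half_up(results$mean_post, 1),
                         round_half_up(results$sd_post, 1)),
    difference = sprintf("%.1f", round_half_up(results$difference, 1)),
    category = results$category
  )
}
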