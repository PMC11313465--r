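#' Specify a randomized multiple-baseline design
#'
#' In a multiple-baseline single-case design the intervention start is
#' staggered: each participant is randomized to one of a set of candidate
#' baseline durations, so an intervention effect can be separated from
#' secular time trends. This constructor records the design and its seed;
#' all downstream randomization (allocation, Monte Carlo testing) flows
#' from it.
#'
#' @param participants Character vector of participant ids.
#' @param group Group label per participant (e.g. `"PS"`/`"NPS"` for with /
#'   without participatory support).
#' @param candidate_durations Candidate baseline durations in days.
#' @param intervention_weeks Length of the intervention phase (weeks).
#' @param followup_days Length of the post-intervention measurement block.
#' @param measurement_weeks Intervention weeks with a 7-day measurement
#'   block. The default measures weeks 1, 8 and 15 of a 15-week program.
#' @param seed Integer seed for reproducible allocation.
#' @return An object of class `mb_design`.
#' @export
design_spec <- function(participants, group,
                        candidate_durations = c(4, 6, 8, 10, 12, 14),
                        intervention_weeks = 15, followup_days = 7,
                        measurement_weeks = c(1, 8, 15), seed = NULL) {
  stopifnot(length(participants) == length(group), !anyDuplicated(participants))
  if (length(candidate_durations) == 0 || any(candidate_durations < 1)) {
    abort("candidate_durations must be non-empty and all >= 1")
  }
  structure(list(
    participants = as.character(participants),
    group = as.character(group),
    candidate_durations = sort(unique(candidate_durations)),
    intervention_weeks = intervention_weeks,
    followup_days = followup_days,
    measurement_weeks = measurement_weeks,
    seed = seed
  ), class = "mb_design")
}

#' @export
print.mb_design <- function(x, ...) {
  cat(sprintf("Multiple-baseline design: %d participants (%s)\n",
              length(x$participants),
              paste(sprintf("%s n=%d", names(table(x$group)), table(x$group)),
                    collapse = ", ")))
  cat(sprintf("  candidate baseline durations: %s days\n",
              paste(x$candidate_durations, collapse = ", ")))
  cat(sprintf("  intervention %d weeks (measured weeks %s), follow-up %d days\n",
              x$intervention_weeks,
              paste(x$measurement_weeks, collapse = ", "), x$followup_days))
  invisible(x)
}

#' Randomize baseline durations
#'
#' @param design An [design_spec()] object.
#' @param mode `"independent"` draws each participant's duration uniformly
#'   and independently from the candidate set (the allocation wording used
#'   in staggered-start studies); `"balanced"` assigns a random permutation
#'   of the candidate set itself (requires the number of participants to be
#'   a multiple of the number of candidates), which guarantees distinct
#'   start points within a group.
#' @return Named integer vector of baseline durations (days) per participant.
#' @export
allocate_baselines <- function(design, mode = c("independent", "balanced")) {
  mode <- match.arg(mode)
  n <- length(design$participants)
  cand <- design$candidate_durations
  durs <- with_seed(design$seed, {
    if (mode == "independent") {
      resample(cand, n, replace = TRUE)
    } else {
      if (n %% length(cand) != 0) {
        abort("balanced allocation needs participants to be a multiple of the candidate count")
      }
      resample(rep(cand, n / length(cand)))
    }
  })
  setNames(as.integer(durs), design$participants)
}

#' Measurement schedule for one participant
#'
#' Baseline days are measured daily; the intervention phase is measured in
#' 7-day blocks at the configured weeks; a follow-up block is measured
#' after the intervention ends. Day indices are calendar days counted from
#' the first baseline day; the intervention starts on day
#' `baseline_days + 1`.
#'
#' @param baseline_days Realized baseline duration (days).
#' @inheritParams design_spec
#' @return Tibble with columns `day` and `phase` (`A`, `B`, `Ap`).
#' @export
measurement_schedule <- function(baseline_days, intervention_weeks = 15,
                                 measurement_weeks = c(1, 8, 15),
                                 followup_days = 7) {
  a <- tibble(day = seq_len(baseline_days), phase = "A")
  b <- bind_rows(lapply(measurement_weeks, function(w) {
    tibble(day = baseline_days + (w - 1) * 7 + seq_len(7), phase = "B")
  }))
  ap <- tibble(day = baseline_days + intervention_weeks * 7 + seq_len(followup_days),
               phase = "Ap")
  bind_rows(a, b, ap)
}

#' Label measured days with study phases
#'
#' @param metrics Tibble of measured days with a `day` column (calendar day
#'   index from the start of measurement).
#' @param baseline_days Days 1..`baseline_days` are phase A (baseline).
#' @param intervention_end_index Last calendar day of phase B; later days
#'   are phase A' (post-intervention).
#' @return `metrics` with a `phase` column. Invalid days keep their
#'   calendar position; analysis functions exclude them via their `valid`
#'   flag.
#' @export
label_phases <- function(metrics, baseline_days, intervention_end_index) {
  if (baseline_days >= max(metrics$day)) {
    abort("baseline_days must be smaller than the last measured day")
  }
  metrics$phase <- ifelse(metrics$day <= baseline_days, "A",
                          ifelse(metrics$day <= intervention_end_index, "B", "Ap"))
  metrics
}

#' The assignment space of a staggered-start randomization
#'
#' @param durations Named vector of realized baseline durations.
#' @param mode `"within_set"` (the Wampold-Worsham scheme): all distinct
#'   permutations of the realized multiset of durations across
#'   participants. `"product"`: every combination from the full candidate
#'   set independently per participant.
#' @param candidate_durations Candidate set (required for `"product"`).
#' @param materialize_limit Assignments are enumerated into a matrix only
#'   when the space is at most this large; the count is always returned.
#' @return A list of class `mb_permspace` with elements `count`,
#'   `assignments` (matrix of duration values, or `NULL` if too large) and
#'   `sample_assignment()` (draws one random assignment).
#' @export
permutation_space <- function(durations, mode = c("within_set", "product"),
                              candidate_durations = NULL,
                              materialize_limit = 1e6) {
  mode <- match.arg(mode)
  n <- length(durations)
  if (mode == "within_set") {
    count <- multiset_count(durations)
    assignments <- if (count <= materialize_limit) {
      multiset_permutations(unname(durations), limit = materialize_limit)
    }
    sampler <- function() resample(unname(durations))
  } else {
    if (is.null(candidate_durations)) {
      abort("candidate_durations is required for the product assignment space")
    }
    m <- length(candidate_durations)
    count <- m^n
    assignments <- if (count <= materialize_limit) {
      as.matrix(expand.grid(rep(list(candidate_durations), n),
                            KEEP.OUT.ATTRS = FALSE))
    }
    sampler <- function() resample(candidate_durations, n, replace = TRUE)
  }
  if (!is.null(assignments)) {
    dimnames(assignments) <- list(NULL, names(durations))
  }
  structure(list(count = count, assignments = assignments,
                 sample_assignment = sampler, mode = mode,
                 durations = durations),
            class = "mb_permspace")
}

#' @export
print.mb_permspace <- function(x, ...) {
  cat(sprintf("Assignment space (%s): %.0f assignment(s) for %d participants%s\n",
              x$mode, x$count, length(x$durations),
              if (is.null(x$assignments)) " (not materialized)" else ""))
  invisible(x)
}
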