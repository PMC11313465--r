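#' Baseline-to-post change for one participant
#'
#' The per-participant statistic of the staggered-start randomization test:
#' the mean of the outcome over valid days after a hypothetical
#' intervention start minus the mean over valid days before it. For the
#' realized baseline duration this is simply the post-minus-baseline change
#' (negative = reduction).
#'
#' @param series Tibble of one participant's measured days with columns
#'   `day` (calendar index), `valid`, and the outcome.
#' @param outcome Name of the outcome column.
#' @param baseline_days Hypothetical baseline duration: days with index
#'   `<= baseline_days` count as "pre".
#' @return The effect in outcome units.
#' @export
participant_effect <- function(series, outcome, baseline_days) {
  v <- series[[outcome]][series$valid]
  d <- series$day[series$valid]
  pre <- v[d <= baseline_days]
  post <- v[d > baseline_days]
  if (length(pre) == 0 || length(post) == 0) {
    abort(sprintf(
      "no valid days on the %s side of a start at day %d",
      if (length(pre) == 0) "baseline" else "post", baseline_days
    ))
  }
  mean(post) - mean(pre)
}

# Effect of every participant under every distinct candidate split point.
# A split that leaves a participant (typically a dropout with a short
# series) without days on one side yields NA; the group statistic then
# averages over the participants that can be split there.
effects_matrix <- function(data, outcome, ids, split_points) {
  E <- matrix(NA_real_, length(ids), length(split_points),
              dimnames = list(ids, split_points))
  for (i in seq_along(ids)) {
    s <- data[data$id == ids[i], , drop = FALSE]
    v <- s[[outcome]][s$valid]
    d <- s$day[s$valid]
    for (j in seq_along(split_points)) {
      pre <- v[d <= split_points[j]]
      post <- v[d > split_points[j]]
      if (length(pre) > 0 && length(post) > 0) {
        E[i, j] <- mean(post) - mean(pre)
      }
    }
  }
  E
}

#' Wampold-Worsham randomization test for a group
#'
#' Tests the null hypothesis of no intervention effect on a daily outcome
#' against a two-tailed alternative. The test statistic is the unweighted
#' mean of per-participant baseline-to-post changes. Its reference
#' distribution is obtained by recomputing the statistic under every
#' admissible reassignment of the staggered baseline durations: by default
#' all distinct permutations of the realized multiset of durations across
#' participants (the within-set scheme). The two-tailed p-value is the
#' share of assignments whose absolute statistic is at least the observed
#' one; the observed assignment is always counted, so p is never zero.
#'
#' When the assignment space is larger than `exact_limit`, assignments are
#' sampled with replacement (Monte Carlo) and the observed assignment is
#' included once: p = (1 + #extreme) / (1 + n_mc).
#'
#' @param data Long tibble of measured days with columns `id`, `day`,
#'   `valid` and the outcome.
#' @param outcome Name of the outcome column.
#' @param durations Named vector of realized baseline durations (days) per
#'   participant id; every id must appear in `data`.
#' @param mode `"auto"` (exact when the space is small enough),
#'   `"exact"`, or `"monte_carlo"`.
#' @param space Assignment space, see [permutation_space()].
#' @param candidate_durations Candidate set (for `space = "product"`).
#' @param strata Optional named vector mapping each id to a stratum;
#'   durations are then permuted only within strata.
#' @param n_mc Number of Monte Carlo assignments.
#' @param seed Seed for Monte Carlo sampling.
#' @param exact_limit Largest space enumerated exhaustively under
#'   `mode = "auto"`.
#' @return An object of class `mb_rtest`.
#' @export
group_test <- function(data, outcome, durations,
                       mode = c("auto", "exact", "monte_carlo"),
                       space = c("within_set", "product"),
                       candidate_durations = NULL, strata = NULL,
                       n_mc = 10000, seed = NULL, exact_limit = 1e6) {
  mode <- match.arg(mode)
  space <- match.arg(space)
  ids <- names(durations)
  if (length(ids) < 2) {
    abort("group_test needs at least 2 participants")
  }
  missing_ids <- setdiff(ids, unique(data$id))
  if (length(missing_ids) > 0) {
    abort(sprintf("no data for participant(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }

  split_points <- if (space == "product") {
    sort(unique(candidate_durations))
  } else {
    sort(unique(unname(durations)))
  }
  E <- effects_matrix(data, outcome, ids, split_points)
  obs_col <- match(durations, split_points)
  obs_effects <- E[cbind(seq_along(ids), obs_col)]
  if (anyNA(obs_effects)) {
    abort(sprintf(
      "participant(s) %s have no valid days on one side of their realized start",
      paste(ids[is.na(obs_effects)], collapse = ", ")
    ))
  }
  observed <- mean(obs_effects)
  if (anyNA(E)) {
    inform(sprintf(
      "%d participant(s) cannot be split at every candidate start (short series); affected assignments average over the remaining participants",
      sum(apply(is.na(E), 1, any))
    ))
  }

  count <- space_count(durations, space, candidate_durations, strata)
  use_exact <- switch(mode,
    exact = TRUE,
    monte_carlo = FALSE,
    auto = count <= exact_limit
  )
  tol <- 1e-9 * max(1, abs(observed))

  if (use_exact) {
    A <- enumerate_assignments(durations, space, candidate_durations, strata,
                               limit = exact_limit)
    idx <- matrix(match(A, split_points), nrow = nrow(A))
    stats <- rowMeans(matrix(E[cbind(rep(seq_along(ids), each = nrow(A)),
                                     as.vector(idx))],
                             nrow = nrow(A)), na.rm = TRUE)
    n_extreme <- sum(abs(stats) >= abs(observed) - tol)
    n_assign <- nrow(A)
    p <- n_extreme / n_assign
    mc_used <- NULL
  } else {
    sampler <- assignment_sampler(durations, space, candidate_durations, strata)
    stats <- with_seed(seed, {
      vapply(seq_len(n_mc), function(k) {
        a <- sampler()
        mean(E[cbind(seq_along(ids), match(a, split_points))], na.rm = TRUE)
      }, numeric(1))
    })
    n_extreme <- 1 + sum(abs(stats) >= abs(observed) - tol)
    n_assign <- n_mc + 1
    p <- n_extreme / n_assign
    mc_used <- n_mc
  }
  if (count <= 1) {
    warn("degenerate assignment space (a single assignment); p = 1")
  }

  structure(list(
    outcome_name = outcome,
    statistic_observed = observed,
    n_assignments = n_assign,
    n_as_extreme = n_extreme,
    p_two_tailed = p,
    mode = if (use_exact) "exact" else "monte_carlo",
    n_mc = mc_used,
    seed = seed,
    space = space,
    space_count = count,
    n_participants = length(ids)
  ), class = "mb_rtest")
}

#' @export
print.mb_rtest <- function(x, ...) {
  cat(sprintf("Randomization test (%s, %s space): %s\n", x$mode, x$space,
              x$outcome_name))
  cat(sprintf("  observed mean change: %.3f over %d participants\n",
              x$statistic_observed, x$n_participants))
  cat(sprintf("  p (two-tailed) = %.4g  [%d of %d assignments as extreme]\n",
              x$p_two_tailed, x$n_as_extreme, x$n_assignments))
  invisible(x)
}

#' Smallest attainable p-value of a design
#'
#' The granularity of a randomization test is set by the size of its
#' assignment space: if the observed assignment is uniquely the most
#' extreme, p = 1 / (number of assignments). Designs are adequate when this
#' floor is below the planned significance level.
#'
#' @inheritParams group_test
#' @return The minimal attainable two-tailed p-value.
#' @export
min_attainable_p <- function(durations, space = c("within_set", "product"),
                             candidate_durations = NULL, strata = NULL) {
  space <- match.arg(space)
  1 / space_count(durations, space, candidate_durations, strata)
}

space_count <- function(durations, space, candidate_durations = NULL,
                        strata = NULL) {
  if (space == "product") {
    return(length(candidate_durations)^length(durations))
  }
  if (is.null(strata)) {
    return(multiset_count(unname(durations)))
  }
  strata <- strata[names(durations)]
  prod(vapply(split(unname(durations), strata), multiset_count, numeric(1)))
}

enumerate_assignments <- function(durations, space, candidate_durations = NULL,
                                  strata = NULL, limit = 1e6) {
  ids <- names(durations)
  if (space == "product") {
    A <- as.matrix(expand.grid(rep(list(candidate_durations), length(ids)),
                               KEEP.OUT.ATTRS = FALSE))
    colnames(A) <- ids
    return(A)
  }
  if (is.null(strata)) {
    A <- multiset_permutations(unname(durations), limit = limit)
    colnames(A) <- ids
    return(A)
  }
  strata <- factor(strata[ids])
  mats <- lapply(split(unname(durations), strata), multiset_permutations,
                 limit = limit)
  grid <- expand.grid(lapply(mats, function(m) seq_len(nrow(m))),
                      KEEP.OUT.ATTRS = FALSE)
  A <- matrix(NA_real_, nrow(grid), length(ids), dimnames = list(NULL, ids))
  for (l in levels(strata)) {
    A[, ids[strata == l]] <- mats[[l]][grid[[l]], , drop = FALSE]
  }
  A
}

assignment_sampler <- function(durations, space, candidate_durations = NULL,
                               strata = NULL) {
  ids <- names(durations)
  if (space == "product") {
    return(function() setNames(resample(candidate_durations, length(ids),
                                      replace = TRUE), ids))
  }
  if (is.null(strata)) {
    return(function() setNames(resample(unname(durations)), ids))
  }
  strata <- factor(strata[ids])
  function() {
    out <- durations
    for (l in levels(strata)) {
      sel <- strata == l
      out[sel] <- resample(unname(durations[sel]))
    }
    out
  }
}
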