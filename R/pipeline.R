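#' Run the full multiple-baseline analysis pipeline
#'
#' Orchestrates an end-to-end run: obtain a cohort (either a directory of
#' event/diary/design files, or a synthetic one generated on the fly),
#' derive daily metrics through the event-processing path, label phases,
#' run the randomization test per outcome for the whole cohort and each
#' group, compute PEM effect sizes with a report-style table and
#' improvement rollup, analyse what replaced sedentary time among
#' improvers, render per-participant band figures, and write a manifest
#' recording the seed and a configuration hash so a run can be reproduced
#' bit for bit.
#'
#' @param out_dir Output directory for the report bundle.
#' @param synthetic A [synthetic_config()] used when `events_dir` is
#'   `NULL`; its cohort is materialized under `out_dir/fixtures` and then
#'   read back through the same file-parsing path as real data.
#' @param events_dir Directory containing `<id>_events.csv` files,
#'   `diary.csv` and `design.yaml` (the layout written by
#'   [generate_cohort()]).
#' @param outcomes Named character vector of outcome columns and their
#'   improvement direction (passed to [cohort_pem()] and the tests).
#' @param pem_threshold PEM cutoff defining an "improver".
#' @param n_mc Monte Carlo assignments when the space is too large for
#'   exact enumeration.
#' @param seed Master seed for all randomness in the analysis stage.
#' @param figures Render per-participant figures?
#' @param figure_formats Formats passed to [render_series()].
#' @param mvpa_cadence,min_wear_hours Passed to [days_metrics()].
#' @return List of class `mb_run` with the computed tables and the paths
#'   written.
#' @export
run_pipeline <- function(out_dir,
                         synthetic = synthetic_config(),
                         events_dir = NULL,
                         outcomes = c(sedentary_hours = "lower_is_better",
                                      fragmentation_index = "higher_is_better"),
                         pem_threshold = 60, n_mc = 10000, seed = 1,
                         figures = TRUE, figure_formats = c("svg", "csv"),
                         mvpa_cadence = 100, min_wear_hours = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(events_dir)) {
    events_dir <- file.path(out_dir, "fixtures")
    generate_cohort(synthetic, dir = events_dir)
  }
  cohort <- load_cohort(events_dir, mvpa_cadence = mvpa_cadence,
                        min_wear_hours = min_wear_hours)
  data <- cohort$data
  durations <- cohort$durations

  readr::write_csv(data, file.path(out_dir, "metrics.csv"), progress = FALSE)

  # randomization tests: each outcome, for all participants and per group
  sets <- c(list(all = unique(data$id)),
            split(unique(data[, c("id", "group")])$id,
                  unique(data[, c("id", "group")])$group))
  tests <- list()
  k <- 0
  for (oc in names(outcomes)) {
    for (set_name in names(sets)) {
      k <- k + 1
      ids <- sets[[set_name]]
      res <- group_test(data[data$id %in% ids, ], oc, durations[ids],
                        n_mc = n_mc, seed = seed + k)
      tests[[paste(oc, set_name, sep = ".")]] <- list(
        outcome = oc, analysis_set = set_name,
        statistic = res$statistic_observed, p = res$p_two_tailed,
        mode = res$mode, n_assignments = res$n_assignments,
        seed = if (res$mode == "monte_carlo") seed + k else NULL
      )
    }
  }
  jsonlite::write_json(tests, file.path(out_dir, "randomization_tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pem_primary <- cohort_pem(data, outcomes)
  readr::write_csv(pem_table(pem_primary), file.path(out_dir, "pem_table.csv"),
                   progress = FALSE)
  rollup <- improvement_rollup(pem_primary, threshold = pem_threshold)
  jsonlite::write_json(list(counts = rollup$counts, improvers = rollup$improvers,
                            threshold = pem_threshold),
                       file.path(out_dir, "rollup.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  pem_activity <- cohort_pem(data, c(lpa_hours = "higher_is_better",
                                     mvpa_minutes = "higher_is_better"))
  replacement <- replacement_analysis(bind_rows(pem_primary, pem_activity),
                                      threshold = pem_threshold)
  jsonlite::write_json(replacement, file.path(out_dir, "replacement.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  fig_files <- character()
  if (figures) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    for (pid in unique(data$id)) {
      for (oc in names(outcomes)) {
        prefix <- file.path(fig_dir, paste0(pid, "_", oc))
        w <- render_series(data[data$id == pid, ], oc, outcomes[[oc]],
                           path_prefix = prefix, formats = figure_formats,
                           title = pid)
        fig_files <- c(fig_files, w)
      }
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mbsced")),
    seed = seed,
    n_mc = n_mc,
    pem_threshold = pem_threshold,
    outcomes = as.list(outcomes),
    config_hash = rlang::hash(list(outcomes, pem_threshold, n_mc, seed,
                                   durations, mvpa_cadence, min_wear_hours)),
    data_hash = rlang::hash(data),
    n_participants = length(durations),
    durations = as.list(durations),
    note = paste("Multiple outcomes are reported without multiplicity",
                 "adjustment, as is conventional for confirmatory",
                 "single-case randomization tests.")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(
    data = data, durations = durations, tests = tests, pem = pem_primary,
    pem_activity = pem_activity, rollup = rollup, replacement = replacement,
    manifest = manifest, out_dir = out_dir, figures = fig_files
  ), class = "mb_run")
}

#' Load a cohort from an events/diary/design directory
#'
#' Reads the file layout written by [generate_cohort()]: one
#' `<id>_events.csv` per participant, a shared `diary.csv` and a
#' `design.yaml` with group labels and realized baseline durations. Events
#' are windowed by the diary, daily metrics computed, and phases labelled
#' from each participant's baseline duration and the intervention length.
#'
#' @inheritParams run_pipeline
#' @param dir The cohort directory.
#' @return List with `data` (long metrics tibble) and `durations`.
#' @export
load_cohort <- function(dir, mvpa_cadence = 100, min_wear_hours = 10) {
  design <- yaml::read_yaml(file.path(dir, "design.yaml"))
  diary <- read_diary(file.path(dir, "diary.csv"))
  durations <- unlist(design$baseline_days)
  start_date <- min(diary$date)
  rows <- lapply(seq_along(design$participants), function(i) {
    pid <- design$participants[[i]]
    ev <- read_events(file.path(dir, paste0(pid, "_events.csv")),
                      dialect = "activpal_events")
    wd <- split_waking_days(ev, diary[diary$participant_id == pid, ])
    m <- days_metrics(wd, mvpa_cadence = mvpa_cadence,
                      min_wear_hours = min_wear_hours)
    m$day <- as.integer(m$date - start_date + 1)
    m <- label_phases(m, durations[[pid]],
                      durations[[pid]] + design$intervention_weeks * 7)
    dplyr::bind_cols(tibble(id = pid, group = design$group[[i]]), m)
  })
  list(data = bind_rows(rows), durations = durations[design$participants])
}

#' What replaced sedentary time among improvers
#'
#' Among participants whose sedentary-time PEM exceeds the threshold (the
#' "improvers"), classifies each by whether their light physical activity,
#' their moderate-to-vigorous activity, both, or neither also improved
#' (PEM above the same threshold), and reports the share of improvers in
#' each category.
#'
#' @param pem_results PEM tibble covering at least the outcomes
#'   `sedentary_hours`, `lpa_hours` and `mvpa_minutes`.
#' @param threshold PEM improvement cutoff.
#' @return Tibble with `category` (`both`, `lpa_only`, `mvpa_only`,
#'   `neither`), `n` and `share_pct` (share of sedentary-time improvers).
#' @export
replacement_analysis <- function(pem_results, threshold = 60) {
  sed <- pem_results[pem_results$outcome_name == "sedentary_hours", ]
  improvers <- sed$id[sed$pem > threshold]
  if (length(improvers) == 0) {
    warn("no sedentary-time improvers; replacement analysis is empty")
    return(tibble(category = character(), n = integer(), share_pct = numeric()))
  }
  improved_on <- function(oc) {
    d <- pem_results[pem_results$outcome_name == oc, ]
    d$id[d$pem > threshold]
  }
  lpa <- improved_on("lpa_hours")
  mvpa <- improved_on("mvpa_minutes")
  cat_of <- function(pid) {
    l <- pid %in% lpa
    m <- pid %in% mvpa
    if (l && m) "both" else if (l) "lpa_only" else if (m) "mvpa_only" else "neither"
  }
  cats <- vapply(improvers, cat_of, character(1))
  tab <- table(factor(cats, levels = c("both", "lpa_only", "mvpa_only", "neither")))
  tibble(category = names(tab), n = as.integer(tab),
         share_pct = 100 * as.integer(tab) / length(improvers))
}

#' @export
print.mb_run <- function(x, ...) {
  cat(sprintf("Multiple-baseline analysis run: %d participants, output in %s\n",
              length(x$durations), x$out_dir))
  for (t in x$tests) {
    cat(sprintf("  %s [%s]: mean change %+.2f, p = %.4g (%s)\n",
                t$outcome, t$analysis_set, t$statistic, t$p, t$mode))
  }
  print(x$rollup)
  invisible(x)
}
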