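#' Reference per-participant effect-size summary
#'
#' A bundled summary table from a completed 14-participant randomized
#' multiple-baseline study of a blended behavioral intervention to reduce
#' and interrupt sedentary time after stroke: per participant and outcome,
#' the percentage-exceeding-the-median effect size, the phase means and
#' sample SDs for baseline (A) and the combined intervention and
#' post-intervention phases (B+A'), and the improvement-signed difference,
#' at the one-decimal precision of the study report. Half of the
#' participants (`PS`) received participatory support from their social
#' network; one `NPS` participant dropped out after five intervention weeks
#' and is included by intention to treat.
#'
#' The raw event streams behind these summaries are not publicly available;
#' the table serves to validate rollup and report-formatting logic against
#' published-scale numbers and to parameterize realistic synthetic cohorts.
#'
#' @return Tibble with columns `group`, `id`, `outcome_name`, `direction`,
#'   `pem`, `mean_A`, `sd_A`, `mean_post`, `sd_post`, `difference`,
#'   `dropout`.
#' @export
reference_cohort_summary <- function() {
  path <- system.file("extdata", "reference_cohort_pem.csv", package = "mbsced",
                      mustWork = TRUE)
  out <- readr::read_csv(path, col_types = readr::cols(
    group = readr::col_character(), id = readr::col_character(),
    outcome_name = readr::col_character(), pem = readr::col_double(),
    mean_A = readr::col_double(), sd_A = readr::col_double(),
    mean_post = readr::col_double(), sd_post = readr::col_double(),
    difference = readr::col_double(), dropout = readr::col_logical()
  ), progress = FALSE)
  out$direction <- ifelse(out$outcome_name == "sedentary_hours",
                          "lower_is_better", "higher_is_better")
  out$category <- classify_pem(out$pem)
  out
}
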