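#' Baseline mean and 2-SD band
#'
#' Visual analysis of single-case series is supported by a band at the
#' baseline mean plus/minus two (sample, n - 1) standard deviations drawn
#' across all phases; post days beyond the band on the improvement side are
#' taken as evidence of change. Days exactly on the band edge are not
#' counted as outside (strict inequality).
#'
#' @inheritParams pem
#' @return List of class `mb_band`: `baseline_mean`, `baseline_sd`,
#'   `upper`, `lower`, `n_post_days`,
#'   `n_post_outside_band_in_improvement_direction`.
#' @export
baseline_band <- function(series, outcome,
                          direction = c("lower_is_better", "higher_is_better"),
                          post_phases = c("B", "Ap")) {
  direction <- match.arg(direction)
  v <- series[[outcome]]
  base <- v[series$phase == "A" & series$valid]
  if (length(base) < 2) {
    abort("baseline_band needs at least 2 valid baseline days")
  }
  post <- v[series$phase %in% post_phases & series$valid]
  m <- mean(base)
  s <- sd(base)
  upper <- m + 2 * s
  lower <- m - 2 * s
  outside <- if (direction == "lower_is_better") post < lower else post > upper
  structure(list(
    outcome_name = outcome, direction = direction,
    baseline_mean = m, baseline_sd = s, upper = upper, lower = lower,
    n_post_days = length(post),
    n_post_outside_band_in_improvement_direction = sum(outside)
  ), class = "mb_band")
}

#' @export
print.mb_band <- function(x, ...) {
  cat(sprintf("2-SD band for %s: mean %.2f, band [%.2f, %.2f]\n",
              x$outcome_name, x$baseline_mean, x$lower, x$upper))
  cat(sprintf("  %d of %d post days outside the band toward improvement\n",
              x$n_post_outside_band_in_improvement_direction, x$n_post_days))
  invisible(x)
}

#' Numeric level/trend/overlap descriptors per phase
#'
#' Emits the quantities a visual analyst reads off a single-case graph --
#' per-phase mean (level), ordinary-least-squares slope over day index
#' (trend), SD (variability), and the share of phase days inside the
#' baseline 2-SD band (overlap) -- as numbers rather than prose.
#'
#' @inheritParams baseline_band
#' @return Tibble with one row per phase.
#' @export
phase_descriptors <- function(series, outcome,
                              direction = c("lower_is_better", "higher_is_better")) {
  direction <- match.arg(direction)
  band <- baseline_band(series, outcome, direction)
  s <- series[series$valid, , drop = FALSE]
  bind_rows(lapply(unique(s$phase), function(ph) {
    d <- s[s$phase == ph, ]
    v <- d[[outcome]]
    slope <- if (nrow(d) > 1) unname(stats::coef(stats::lm(v ~ d$day))[2]) else NA_real_
    tibble(
      phase = ph, n_days = nrow(d), level = mean(v),
      sd = if (nrow(d) > 1) sd(v) else NA_real_,
      trend_per_day = slope,
      pct_in_band = 100 * mean(v >= band$lower & v <= band$upper)
    )
  }))
}

#' Render a single-case series with phase marks and 2-SD band
#'
#' Draws the day-indexed outcome series with vertical lines at the start
#' and end of the intervention phase, a solid line at the baseline mean and
#' dashed lines at the 2-SD band, in the style conventional for
#' multiple-baseline study reports. Writes the figure (SVG and/or PNG) and
#' a plot-data CSV containing exactly the analysis-set days that were
#' drawn, so the figure can be audited and regenerated.
#'
#' @inheritParams baseline_band
#' @param path_prefix Output path without extension.
#' @param formats Any of `"svg"`, `"png"`, `"csv"`.
#' @param title Optional panel title.
#' @return Named character vector of the files written, invisibly.
#' @export
render_series <- function(series, outcome,
                          direction = c("lower_is_better", "higher_is_better"),
                          path_prefix, formats = c("svg", "png", "csv"),
                          title = NULL) {
  direction <- match.arg(direction)
  if (nrow(series) == 0) {
    abort("cannot render an empty series")
  }
  band <- baseline_band(series, outcome, direction)
  plot_data <- tibble(
    day = series$day, phase = series$phase, valid = series$valid,
    value = series[[outcome]]
  )
  drawn <- plot_data[plot_data$valid, , drop = FALSE]
  b_days <- drawn$day[drawn$phase == "B"]
  marks <- c(min(b_days) - 0.5, max(b_days) + 0.5)

  p <- ggplot2::ggplot(drawn, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_hline(yintercept = band$baseline_mean, colour = "black") +
    ggplot2::geom_hline(yintercept = c(band$lower, band$upper),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_vline(xintercept = marks, colour = "black") +
    ggplot2::geom_line(ggplot2::aes(group = .data$phase), colour = "grey40") +
    ggplot2::geom_point(size = 1.3) +
    ggplot2::labs(x = "Measurement day", y = outcome, title = title) +
    ggplot2::theme_bw()

  written <- character()
  if ("csv" %in% formats) {
    f <- paste0(path_prefix, ".csv")
    readr::write_csv(plot_data, f, progress = FALSE)
    written["csv"] <- f
  }
  if ("svg" %in% formats) {
    f <- paste0(path_prefix, ".svg")
    grDevices::svg(f, width = 7, height = 3.2)
    print(p)
    grDevices::dev.off()
    written["svg"] <- f
  }
  if ("png" %in% formats) {
    f <- paste0(path_prefix, ".png")
    grDevices::png(f, width = 1400, height = 640, res = 150)
    print(p)
    grDevices::dev.off()
    written["png"] <- f
  }
  invisible(written)
}
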