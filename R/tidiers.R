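#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the 2x2 repeated-measures ANOVA
#'
#' @param x An `"anova_2x2"` object.
#' @param ... Unused.
#' @return A tibble with one row per effect: `term`, `df1`, `df2`,
#'   `statistic`, `p.value`, `eta.p.sq`.
#' @method tidy anova_2x2
#' @export
tidy.anova_2x2 <- function(x, ...) {
  tibble::tibble(term = x$effect, df1 = x$df1, df2 = x$df2,
                 statistic = x$statistic, p.value = x$p_value,
                 eta.p.sq = x$eta_p_sq)
}

#' @rdname tidy.anova_2x2
#' @method glance anova_2x2
#' @export
glance.anova_2x2 <- function(x, ...) {
  tibble::tibble(n = x$df2[1] + 1L,
                 contingency_f = x$statistic[x$effect == "Contingency"],
                 contingency_p = x$p_value[x$effect == "Contingency"])
}

#' Tidy Bayesian model-comparison results
#'
#' @param x A `"bayes_2x2"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per model (`model`, `bf10`, `log.bf10`,
#'   `mc.error`); `glance()`: best model and its BF10.
#' @method tidy bayes_2x2
#' @export
tidy.bayes_2x2 <- function(x, ...) {
  tibble::tibble(model = x$models$model, bf10 = x$models$bf10,
                 log.bf10 = x$models$log_bf10, mc.error = x$models$mc_error)
}

#' @rdname tidy.bayes_2x2
#' @method glance bayes_2x2
#' @export
glance.bayes_2x2 <- function(x, ...) {
  best <- which.max(x$models$bf10)
  tibble::tibble(best_model = x$models$model[best],
                 best_bf10 = x$models$bf10[best],
                 iterations = x$iterations)
}

#' Tidy per-sample permutation-test results
#'
#' @param x A `"perm_result"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per time sample (`time_ms`, `statistic`,
#'   `significant`); `glance()`: the critical values and window count.
#' @method tidy perm_result
#' @export
tidy.perm_result <- function(x, ...) {
  tibble::tibble(time_ms = x$times, statistic = x$t_series,
                 significant = x$sig_mask)
}

#' @rdname tidy.perm_result
#' @method glance perm_result
#' @export
glance.perm_result <- function(x, ...) {
  tibble::tibble(t_crit_low = x$t_crit_low, t_crit_high = x$t_crit_high,
                 n_perm = x$n_perm, alpha = x$alpha,
                 n_subjects = x$n_subjects, n_windows = nrow(x$windows))
}

#' Tidy block-stability results
#'
#' @param x A `"block_anova"` object.
#' @param ... Unused.
#' @return A tibble of the ANOVA effects with Greenhouse-Geisser fields.
#' @method tidy block_anova
#' @export
tidy.block_anova <- function(x, ...) {
  tibble::tibble(term = x$anova$effect, df1 = x$anova$df1,
                 df2 = x$anova$df2, statistic = x$anova$statistic,
                 p.value = x$anova$p_value, eta.p.sq = x$anova$eta_p_sq,
                 gg.epsilon = x$anova$gg_epsilon, p.gg = x$anova$p_gg)
}

#' Plot the permutation t series with critical bounds and windows
#'
#' @param object A `"perm_result"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot perm_result
#' @export
autoplot.perm_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms,
                                        y = .data$statistic)) +
    ggplot2::geom_hline(yintercept = c(object$t_crit_low,
                                       object$t_crit_high),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "t statistic",
                  title = "Per-sample contingency contrast",
                  subtitle = sprintf(
                    "tmax/tmin permutation bounds (%d permutations, alpha = %g)",
                    object$n_perm, object$alpha)) +
    ggplot2::theme_minimal()
  if (nrow(object$windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey30",
      inherit.aes = FALSE)
  }
  p
}

#' Plot a time-frequency power map
#'
#' Averages the map over the given channels and draws a time x frequency
#' raster of percent change (or raw power).
#'
#' @param object A [tf_power] object.
#' @param channels Channels to average (default: occipital ROI channels
#'   present in the object).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tf_power
#' @export
autoplot.tf_power <- function(object, channels = NULL, ...) {
  channels <- channels %||% intersect(roi_channels(), object$channels)
  chsel <- match(channels, object$channels)
  if (anyNA(chsel)) stop("Unknown channels", call. = FALSE)
  m <- apply(object$power[, , chsel, drop = FALSE], c(1, 2), mean)
  df <- tibble::tibble(
    freq_hz = rep(object$freqs, times = length(object$times)),
    time_ms = rep(object$times, each = length(object$freqs)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$freq_hz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(
      name = if (object$normalized) "% change" else "power") +
    ggplot2::labs(x = "Time (ms)", y = "Frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Bar plot of the 2x2 cell means with within-subject error bars
#'
#' @param table An effect table (see [rm_anova_2x2()]).
#' @return A ggplot with Morey-corrected within-subject SEM error bars.
#' @export
plot_alpha_cells <- function(table) {
  sem <- within_subject_sem(table)
  ggplot2::ggplot(sem, ggplot2::aes(x = .data$contingency,
                                    y = .data$mean,
                                    fill = .data$extinction)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Alpha power (% change from baseline)",
                  fill = "Extinction") +
    ggplot2::theme_minimal()
}

#' Plot cohort alpha timecourses by contingency
#'
#' @param timecourses Tibble of per-subject timecourses (rows from
#'   [timecourse_summary()]).
#' @param windows Optional tibble with `start_ms` / `end_ms` columns to
#'   shade (e.g. `perm$windows`).
#' @return A ggplot of the cohort-mean CS+ and CS- series.
#' @export
plot_timecourses <- function(timecourses, windows = NULL) {
  avg <- dplyr::summarise(
    dplyr::group_by(timecourses, .data$contingency, .data$time_ms),
    alpha_pct = mean(.data$alpha_pct), .groups = "drop")
  p <- ggplot2::ggplot(avg, ggplot2::aes(.data$time_ms, .data$alpha_pct,
                                         colour = .data$contingency)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "Alpha power (% change)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(windows) && nrow(windows) > 0) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$start_ms, xmax = .data$end_ms),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey30",
      inherit.aes = FALSE)
  }
  p
}
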