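# ggplot2 graphics for the main result types.

#' Plot a ROC scan
#'
#' Draws the scanned (1 - specificity, sensitivity) points with the
#' ROC-optimal threshold highlighted and the AUC in the subtitle.
#'
#' @param x A `psg_roc` from [roc_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_roc <- function(x, ...) {
  stopifnot(inherits(x, "psg_roc"))
  df <- x$roc
  best <- df[which.max(df$youden), ]
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity (false positive rate)",
      y = "Sensitivity",
      title = "ROC threshold scan (sleep as positive class)",
      subtitle = sprintf("AUC = %.3f; ROT = %.4g", x$auc, x$rot)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object A `psg_roc`.
#' @method autoplot psg_roc
#' @export
autoplot.psg_roc <- function(object, ...) plot_roc(object, ...)

#' Plot an amplitude envelope with optional events
#'
#' @param env A `psg_envelope` from [amplitude_envelope()].
#' @param events Optional event tibble (`onset_sec`, `duration_sec`,
#'   `type`) drawn as shaded intervals.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_envelope <- function(env, events = NULL, ...) {
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$time_sec, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Time (s)", y = "Amplitude (max - min per 5-s window)",
                  title = "Respiratory amplitude envelope") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    ev <- dplyr::mutate(events, end_sec = .data$onset_sec + .data$duration_sec)
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_sec, xmax = .data$end_sec,
                   ymin = -Inf, ymax = Inf, fill = .data$type),
      alpha = 0.25
    ) + ggplot2::labs(fill = "Event")
  }
  p
}

#' @rdname plot_envelope
#' @param object A `psg_envelope`.
#' @method autoplot psg_envelope
#' @export
autoplot.psg_envelope <- function(object, ...) plot_envelope(object, ...)

#' Plot predicted awake/sleep staging against an expert hypnogram
#'
#' @param staging Tibble from [stage_record()] (`epoch_index`, `sleep`).
#' @param expert Optional expert hypnogram ([hypnogram()]) or 0/1 vector.
#' @return A ggplot object.
#' @export
plot_staging <- function(staging, expert = NULL) {
  df <- tibble(epoch_index = staging$epoch_index,
               value = staging$sleep, series = "algorithm")
  if (!is.null(expert)) {
    ev <- if (inherits(expert, "psg_hypnogram") ||
                (is.data.frame(expert) && "stage" %in% names(expert))) {
      binarize_stages(expert)
    } else {
      as.integer(expert)
    }
    df <- dplyr::bind_rows(df, tibble(
      epoch_index = seq_along(ev) - 1L, value = ev, series = "expert"
    ))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch_index, y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~series, ncol = 1) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c("awake", "sleep")) +
    ggplot2::labs(x = "Epoch (30 s)", y = NULL, title = "Awake/sleep staging") +
    ggplot2::theme_minimal()
}

#' Plot pooled calibration points and the fitted regression
#'
#' @param points Tibble with `rot_norm`, `fpt_norm` (e.g.
#'   `calibrate_cohort()$points` or [synth_threshold_points()]).
#' @param regression Optional `psg_fpt_regression` to overlay.
#' @return A ggplot object.
#' @export
plot_fpt_regression <- function(points, regression = NULL) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$rot_norm, y = .data$fpt_norm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "ROT / power max", y = "FPT / power max",
                  title = "Normalized FPT vs ROT calibration points") +
    ggplot2::theme_minimal()
  if (!is.null(regression)) {
    p <- p + ggplot2::geom_abline(slope = regression$slope,
                                  intercept = regression$intercept,
                                  colour = "red") +
      ggplot2::labs(subtitle = sprintf("slope %.3f, intercept %.3f, R2 %.3f",
                                       regression$slope, regression$intercept,
                                       regression$r2))
  }
  p
}
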