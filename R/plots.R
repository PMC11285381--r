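#' Plot a cosinor fit over the activity series
#'
#' @param object A [cosinor_fit][fit_cosinor()].
#' @param data Optional activity (vector or single-subject tibble) to draw
#'   behind the fitted curve.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cosinor_fit <- function(object, data = NULL, ...) {
  df <- tibble::tibble(t = seq_len(object$n), fitted = object$fitted)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t))
  if (!is.null(data)) {
    df$activity <- pull_activity(data)
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = .data$activity), data = df,
      colour = "grey70", linewidth = 0.2
    )
  }
  p +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#2166ac",
                       linewidth = 0.8) +
    ggplot2::labs(x = "epoch (min)", y = "activity counts",
                  title = "Cosinor fit")
}

#' Plot detected sleep/wake cycles for one subject
#'
#' Activity trace with detected sleep periods shaded and onset events
#' marked: the standard visual check that the detected cycles track the
#' rest-activity pattern.
#'
#' @param object An [sw_detection][detect_subject()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sw_detection <- function(object, ...) {
  df <- tibble::tibble(
    timestamp = object$start_time + 60 * (seq_len(object$n) - 1),
    activity = object$activity
  )
  ev <- object$events
  lab <- sw_labels(object$n, ev$epoch,
                   ifelse(ev$kind == "SOT", "to_sleep", "to_wake"))
  r <- rle(lab == "sleep")
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  shade <- tibble::tibble(
    xmin = df$timestamp[lo[r$values]],
    xmax = df$timestamp[hi[r$values]]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp)) +
    ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "#4393c3", alpha = 0.2
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$activity),
                       colour = "grey40", linewidth = 0.2) +
    ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$timestamp,
                   colour = .data$kind),
      linewidth = 0.4
    ) +
    ggplot2::scale_colour_manual(values = c(SOT = "#b2182b",
                                            WOT = "#1a9850")) +
    ggplot2::labs(x = NULL, y = "activity counts", colour = "onset",
                  title = sprintf("Detected sleep-wake cycles: subject %s",
                                  object$subject_id))
}

#' Bland–Altman plot of event-marker agreement
#'
#' Difference between estimated and marker minutes against their mean,
#' with the bias and 95% limits of agreement, faceted by event kind.
#'
#' @param matches Output of [match_markers()].
#' @return A ggplot.
#' @export
plot_bland_altman <- function(matches) {
  pairs <- matches[!is.na(matches$diff), ]
  summ <- summarize_agreement(matches)
  ggplot2::ggplot(
    pairs,
    ggplot2::aes(x = (.data$est_min + .data$marker_min) / 2,
                 y = .data$diff)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(data = summ,
                        ggplot2::aes(yintercept = .data$bias),
                        colour = "#b2182b") +
    ggplot2::geom_hline(data = summ,
                        ggplot2::aes(yintercept = .data$loa_low),
                        linetype = 2) +
    ggplot2::geom_hline(data = summ,
                        ggplot2::aes(yintercept = .data$loa_high),
                        linetype = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$kind), scales = "free_x") +
    ggplot2::labs(x = "mean of estimate and marker (min since midnight)",
                  y = "estimate - marker (min)",
                  title = "Bland-Altman agreement with event markers")
}
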