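# ggplot2 displays for the main result types.

#' Plot a normalized averaged beat
#'
#' Line plot of the standardized beat with the A-E extrema marked (when
#' detectable).
#'
#' @param object A `normalized_beat`.
#' @param peaks Overlay the detected A-E peaks? Default `TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normalized_beat <- function(object, peaks = TRUE, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frac, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "beat fraction", y = "normalized amplitude") +
    ggplot2::theme_minimal()
  if (peaks) {
    pk <- tryCatch(detect_peaks_abcde(object), error = function(e) NULL)
    if (!is.null(pk)) {
      pk <- pk[pk$present, ]
      pk$amplitude_plot <- object$amplitude[pk$position]
      p <- p +
        ggplot2::geom_point(data = pk,
                            ggplot2::aes(x = .data$frac, y = .data$amplitude_plot),
                            color = "firebrick") +
        ggplot2::geom_text(data = pk,
                           ggplot2::aes(x = .data$frac, y = .data$amplitude_plot,
                                        label = .data$peak),
                           vjust = -0.8, size = 3)
    }
  }
  p
}

#' Plot the regression vector of a PLS calibration curve
#'
#' @param object An `fbg_pls`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fbg_pls <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$frac, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::labs(x = "beat fraction",
                  y = "coefficient (mmHg per unit amplitude)",
                  title = sprintf("PLS regression vector (%d factors)", object$k)) +
    ggplot2::theme_minimal()
}

#' Plot predicted versus reference pressure for an experiment
#'
#' Scatter of predicted against cuff-reference blood pressure for every
#' validation record, faceted by calibration curve, with the identity line.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$reference_bp_mmHg,
                               y = .data$predicted_bp_mmHg,
                               color = .data$subject_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~curve) +
    ggplot2::labs(x = "reference blood pressure (mmHg)",
                  y = "calculated blood pressure (mmHg)",
                  color = "subject") +
    ggplot2::theme_minimal()
}
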