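#' Forest plot of an SCCS fit
#'
#' Dot-and-whisker plot of the incidence-rate ratios (with confidence
#' intervals) on a log scale, one row per model term, with a reference line
#' at IRR 1.
#'
#' @param object An [sccs_fit()] object.
#' @param conf.level Confidence level for the whiskers.
#' @param exposure_only Show only the pre-exposure/exposed terms (drop the
#'   age and season nuisance terms).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sccs_fit
#' @export
autoplot.sccs_fit <- function(object, conf.level = 0.95, exposure_only = TRUE, ...) {
  td <- tidy(object, exponentiate = TRUE, conf.level = conf.level)
  if (exposure_only) {
    td <- td[td$term %in% c("pre_exposure", "exposed"), , drop = FALSE]
  }
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Incidence rate ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Patient exposure timelines
#'
#' Horizontal timeline per patient showing the observation window coloured
#' by exposure category, with the incident event marked. Useful for spot
#' checks of segmentation.
#'
#' @param segments A [classify_exposure()] tibble.
#' @param cases Optional [select_incident_events()] tibble; events are drawn
#'   as points.
#' @param patient_ids Patients to show (default: the first six).
#' @return A ggplot object.
#' @export
plot_timelines <- function(segments, cases = NULL, patient_ids = NULL) {
  if (is.null(patient_ids)) {
    patient_ids <- utils::head(unique(segments$patient_id), 6L)
  }
  seg <- segments[segments$patient_id %in% patient_ids, , drop = FALSE]
  seg$category <- factor(seg$category, levels = .CAT_LEVELS)
  p <- ggplot2::ggplot(seg) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start_date, xend = .data$end_date + 1,
                   y = .data$patient_id, yend = .data$patient_id,
                   colour = .data$category),
      linewidth = 3) +
    ggplot2::labs(x = NULL, y = NULL, colour = "category") +
    ggplot2::theme_minimal()
  if (!is.null(cases)) {
    ev <- cases[cases$patient_id %in% patient_ids, , drop = FALSE]
    if (nrow(ev)) {
      p <- p + ggplot2::geom_point(
        data = ev,
        ggplot2::aes(x = .data$event_date, y = .data$patient_id),
        shape = 4, size = 3, stroke = 1.2, colour = "black")
    }
  }
  p
}
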