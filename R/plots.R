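#' Plot a stage confusion matrix
#'
#' Tile heat map of gold-standard against algorithm CKD stage with cell
#' counts.
#'
#' @param object a [stage_confusion_matrix()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.stage_confusion <- function(object, ...) {
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("gold", "predicted", "n")
  df$gold <- factor(df$gold, levels = rev(.ckd_stage_levels))
  df$predicted <- factor(df$predicted, levels = .ckd_stage_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$gold,
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "algorithm stage", y = "gold-standard stage", fill = "n") +
    ggplot2::theme_minimal()
}

#' Plot an accuracy report
#'
#' Point estimates with their asymptotic confidence intervals.
#'
#' @param object an [accuracy_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.accuracy_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[!df$undefined, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "proportion") +
    ggplot2::theme_minimal()
}

#' Plot per-patient eGFR trajectories
#'
#' Harmonised eGFR series over time with the KDIGO G-stage boundaries as
#' reference lines.
#'
#' @param cohort an [ehr_cohort()].
#' @param patient_ids patients to draw (default: up to 12).
#' @param config a [load_config()] object.
#' @return a ggplot object.
#' @export
plot_egfr_trajectories <- function(cohort, patient_ids = NULL,
                                   config = load_config()) {
  if (is.null(patient_ids)) {
    patient_ids <- utils::head(ckdphen::patient_ids(cohort), 12)
  }
  series <- egfr_series(cohort_subset(cohort, patient_ids), config)
  ggplot2::ggplot(series, ggplot2::aes(x = .data$date, y = .data$egfr,
                                       colour = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = config$thresholds$g_stage_boundaries,
                        linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = NULL, y = "eGFR (mL/min/1.73m2)", colour = "patient") +
    ggplot2::theme_minimal()
}
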