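# ggplot2 figures for the main result types.

#' Plot a simulated time-activity curve
#'
#' Plasma and tissue activity (kBq/mL) against minutes post-injection.
#'
#' @param object An `fdg_tac` tibble from [tissue_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fdg_tac <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("cp_kbq_ml", "ct_kbq_ml"),
                              names_to = "compartment", values_to = "activity")
  long$compartment <- dplyr::recode(long$compartment,
                                    cp_kbq_ml = "plasma", ct_kbq_ml = "tissue")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min, y = .data$activity,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "minutes post-injection", y = "activity (kBq/mL)",
                  colour = NULL,
                  title = "Two-tissue-compartment FDG time-activity curve") +
    ggplot2::theme_minimal()
}

#' Paired AI plot across the two time points
#'
#' One line per patient from AI1 (early) to AI2 (delayed), the dual-time-point
#' analogue of a paired box-line plot; facet by MRI status with
#' `by_mri = TRUE`.
#'
#' @param records AI record tibble from [ai_records()].
#' @param by_mri Facet by MRI status.
#' @return A ggplot object.
#' @export
plot_ai_paired <- function(records, by_mri = FALSE) {
  long <- tidyr::pivot_longer(records, c("ai1", "ai2"),
                              names_to = "timepoint", values_to = "ai")
  long$timepoint <- factor(ifelse(long$timepoint == "ai1", "early", "delayed"),
                           levels = c("early", "delayed"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint, y = .data$ai)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id), alpha = 0.4) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_boxplot(ggplot2::aes(group = .data$timepoint),
                          width = 0.15, outlier.shape = NA, alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "asymmetry index",
                  title = "EZ asymmetry at early vs delayed imaging") +
    ggplot2::theme_minimal()
  if (by_mri) p <- p + ggplot2::facet_wrap(~mri_status)
  p
}

#' Per-patient delta-AI dot plot
#'
#' Delta-AI for every patient, colored by whether the delayed asymmetry
#' increased or decreased.
#'
#' @param records AI record tibble from [ai_records()].
#' @return A ggplot object.
#' @export
plot_delta_ai <- function(records) {
  df <- dplyr::mutate(records, direction = ifelse(.data$dai >= 0, "increased", "decreased"))
  ggplot2::ggplot(df, ggplot2::aes(x = seq_len(nrow(df)), y = .data$dai,
                                   colour = .data$direction)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(increased = "darkorange",
                                            decreased = "darkgreen")) +
    ggplot2::labs(x = "patient", y = expression(Delta * "AI"), colour = NULL,
                  title = "Change in asymmetry index at the delayed time point") +
    ggplot2::theme_minimal()
}

#' Plot a cohort summary
#'
#' Mean AI with SD error bars per stratum and time point.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  tab <- object$table
  long <- dplyr::bind_rows(
    tibble(stratum = tab$stratum, timepoint = "early",
           mean = tab$ai1_mean, sd = tab$ai1_sd),
    tibble(stratum = tab$stratum, timepoint = "delayed",
           mean = tab$ai2_mean, sd = tab$ai2_sd)
  )
  long$timepoint <- factor(long$timepoint, c("early", "delayed"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stratum, y = .data$mean,
                                     fill = .data$timepoint)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = NULL, y = "asymmetry index (mean ± SD)", fill = NULL) +
    ggplot2::theme_minimal()
}
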