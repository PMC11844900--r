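#' Per-participant interval-vs-ROPE responder plot
#'
#' Displays each participant's observed delta with its HDI against the
#' group's ROPE band (shaded), faceted by group and coloured by responder
#' label — the individual-responsiveness display of the decision rule.
#'
#' @param calls Output of [classify_cohort()].
#' @return A ggplot object.
#' @export
plot_responders <- function(calls) {
  calls <- dplyr::arrange(calls, .data$group, .data$delta)
  calls$participant <- factor(calls$participant_id,
                              levels = unique(calls$participant_id))
  rope <- dplyr::distinct(calls, .data$group, .data$rope_lower,
                          .data$rope_upper)
  ggplot2::ggplot(calls, ggplot2::aes(x = .data$participant,
                                      y = .data$delta)) +
    ggplot2::geom_rect(
      data = rope, inherit.aes = FALSE,
      ggplot2::aes(ymin = .data$rope_lower, ymax = .data$rope_upper),
      xmin = -Inf, xmax = Inf, fill = "grey85", alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$hdi_lower, ymax = .data$hdi_upper,
                   colour = .data$label), width = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$label), size = 1.8) +
    ggplot2::facet_wrap(~ group, scales = "free_x") +
    ggplot2::labs(
      x = NULL,
      y = sprintf("%s change from baseline (mmHg)",
                  toupper(unique(calls$outcome))[1]),
      colour = "call",
      title = sprintf("Individual %s responsiveness (%s)",
                      unique(calls$outcome)[1], unique(calls$condition)[1])
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
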