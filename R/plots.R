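#' Plot a screening result
#'
#' Dot plot of per-individual variant read frequencies by roster group with
#' the applied cut-off as a dashed line — the screen's standard visual
#' (carriers are the points above the line).
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot screen_result
#' @export
autoplot.screen_result <- function(object, ...) {
  dat <- object$data |>
    mutate(side = ifelse(.data$group == "SLE", "SLE", "without SLE"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$side, y = 100 * .data$frequency)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$above), width = 0.2,
                         height = 0, size = 1.4, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 100 * object$cutoff$cutoff_applied,
                        linetype = "dashed") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.45,
                          linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(
      x = NULL, y = "variant read frequency (%)",
      title = sprintf("Locus %s: cut-off %.2g%% (mean + 3 SD of controls)",
                      object$locus_id, 100 * object$cutoff$cutoff_applied),
      subtitle = sprintf("two-tailed Fisher exact p = %.3g", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot clinical comparisons between carrier groups
#'
#' Bar chart of -log10 p-values per clinical parameter with the 0.05
#' significance line.
#'
#' @param object A `clinical_comparison` from [compare_clinical()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot clinical_comparison
#' @export
autoplot.clinical_comparison <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$parameter,
                                                  -.data$p_value),
                               y = -log10(.data$p_value))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Clinical parameters by carrier group") +
    ggplot2::theme_minimal()
}
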