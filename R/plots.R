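need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_input("package 'ggplot2' is required for plotting")
  }
}

#' Bland--Altman plot
#'
#' Scatter of per-pair differences against per-pair means, with horizontal
#' lines at the bias and the limits of agreement.
#'
#' @param ba A [bland_altman()] or [method_agreement()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  need_ggplot2()
  stopifnot(inherits(ba, c("bland_altman", "agreement_report")))
  ggplot2::ggplot(ba$table, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods", y = "Difference (UFD - Jesus)",
                  title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g]",
                                  ba$bias, ba$loa_low, ba$loa_high)) +
    ggplot2::theme_minimal()
}

#' Paired-line plot of per-specimen method values
#'
#' One line per specimen connecting its value under each method; visualizes
#' within-subject consistency of the two assessments.
#'
#' @param tbl A long-format table from [paired_lines_table()].
#' @return A ggplot object.
#' @export
plot_paired_lines <- function(tbl) {
  need_ggplot2()
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$method, y = .data$value,
                                    group = .data$specimen_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Compliance estimate") +
    ggplot2::theme_minimal()
}
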