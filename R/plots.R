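#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the AUC response to window size per behaviour
#'
#' Scatter of per-run AUC against window size, facetted by behaviour, with
#' the fitted second-order polynomial overlaid — the standard diagnostic
#' for judging where each behaviour's recognition performance peaks.
#'
#' @param object An `experiment_table` from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot experiment_table
#' @export
autoplot.experiment_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$auc), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_size, y = .data$auc)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x + I(x^2),
                         se = FALSE, linewidth = 0.7, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~behaviour) +
    ggplot2::labs(x = "window size (samples)", y = "ROC AUC",
                  title = "AUC response to window size") +
    ggplot2::theme_minimal()
}

#' Plot fitted window optima against bout medians
#'
#' One point per behaviour: the fitted AUC-optimal window size against the
#' behaviour's median bout length, with the identity line. Points near the
#' line support choosing the bout median as the window size.
#'
#' @param object A `window_optima` tibble from [optimise_windows()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot window_optima
#' @export
autoplot.window_optima <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bout_median_samples,
                                   y = .data$vertex_samples)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "#d95f02") +
    ggplot2::geom_text(ggplot2::aes(label = .data$behaviour),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = "median bout length (samples)",
                  y = "fitted AUC-optimal window (samples)",
                  title = "Window optimum vs bout median") +
    ggplot2::theme_minimal()
}

#' Plot the bout-window vs farthest-window comparison
#'
#' Paired bars per behaviour: mean AUC with the bout-matched window and
#' with the grid window farthest from the bout median.
#'
#' @param report A tibble from [bout_vs_nonbout_report()].
#' @return A ggplot object.
#' @export
plot_bout_comparison <- function(report) {
  long <- report %>%
    dplyr::select("behaviour", "auc_bout_window", "auc_far_window") %>%
    tidyr::pivot_longer(-"behaviour", names_to = "window",
                        values_to = "auc") %>%
    dplyr::mutate(window = dplyr::recode(.data$window,
                                         auc_bout_window = "bout length window",
                                         auc_far_window = "farthest window"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$behaviour, y = .data$auc,
                                     fill = .data$window)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::scale_fill_manual(values = c("bout length window" = "#1b9e77",
                                          "farthest window" = "#7570b3")) +
    ggplot2::labs(x = NULL, y = "mean ROC AUC", fill = NULL,
                  title = "Bout-matched vs farthest window") +
    ggplot2::theme_minimal()
}
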