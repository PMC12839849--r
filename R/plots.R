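
#' Kaplan-Meier plot for a risk report
#'
#' Step curves of the product-limit estimate per risk group.
#'
#' @param object A `risk_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot risk_report
#' @export
autoplot.risk_report <- function(object, ...) {
  km <- object$km |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L,
             n_censor = 0L, surv = 1),
      .x
    )) |>
    dplyr::ungroup()
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", colour = "Risk group",
                  subtitle = sprintf("log-rank p = %.2g, HR = %.2f",
                                     object$logrank$p, object$hazard_ratio$hr)) +
    ggplot2::theme_minimal()
}

#' Waterfall plot of risk scores
#'
#' Samples ordered by risk score, coloured by event status, with the cutoff
#' as a horizontal reference.
#'
#' @param report A `risk_report`.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(report) {
  stopifnot(inherits(report, "risk_report"))
  df <- report$waterfall |>
    dplyr::mutate(status = ifelse(.data$event == 1L, "event", "censored"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$risk_score,
                                   fill = .data$status)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = report$cutoff, linetype = "dashed") +
    ggplot2::labs(x = "Samples (ordered by risk score)", y = "Risk score",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Time-dependent ROC plot
#'
#' @param object A `time_roc` object from [time_dependent_roc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot time_roc
#' @export
autoplot.time_roc <- function(object, ...) {
  roc <- object
  df <- tibble(fpr = 1 - roc$specificity, tpr = roc$sensitivity) |>
    dplyr::arrange(.data$fpr, .data$tpr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path(linewidth = 0.8, colour = "#2166AC") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      subtitle = sprintf("AUC = %.3f at horizon %s", attr(roc, "auc"),
                         attr(roc, "horizon"))
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of a feature-pathway correlation map
#'
#' @param object A `correlation_map`.
#' @param ... Unused.
#' @return A ggplot object with significance stars (raw p < .05, .01, .001).
#' @method autoplot correlation_map
#' @export
autoplot.correlation_map <- function(object, ...) {
  df <- object |>
    dplyr::mutate(stars = dplyr::case_when(
      .data$p < 0.001 ~ "***", .data$p < 0.01 ~ "**",
      .data$p < 0.05 ~ "*", TRUE ~ ""
    ))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathway, y = .data$feature_id,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
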