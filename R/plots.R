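#' Plot the cross-validated threshold search
#'
#' Mean held-out Cox likelihood ratio against the candidate `|score|`
#' thresholds, with the chosen threshold marked.
#'
#' @param object a [cv_select_threshold()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot threshold_search
#' @export
autoplot.threshold_search <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$threshold, y = .data$mean_performance)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$threshold,
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "|Cox score| threshold",
                  y = "mean held-out likelihood ratio",
                  title = "Cross-validated threshold selection") +
    ggplot2::theme_minimal()
}

#' Plot a fitted risk model
#'
#' Selected features ranked by score magnitude, colored by feature kind
#' (gene set vs single gene).
#'
#' @param object a [train_risk_model()] fit.
#' @param top_n how many features to show (default 30).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot risk_model
#' @export
autoplot.risk_model <- function(object, top_n = 30, ...) {
  d <- head(object$selected, top_n)
  d$feature_id <- factor(d$feature_id, levels = rev(d$feature_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$abs_score, y = .data$feature_id,
                                  fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "|Cox score|", y = NULL, fill = "feature kind",
                  title = sprintf("Selected features (threshold %.3g)",
                                  object$search$threshold)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for the median-split risk groups
#'
#' @param risk numeric per-sample risk scores.
#' @param surv aligned `survival_data`.
#' @return A ggplot object with one survival step curve per risk group and
#'   the log-rank p-value in the subtitle.
#' @export
plot_km_split <- function(risk, surv) {
  km <- km_curve_data(risk, surv)
  ls <- logrank_median_split(risk, surv)
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival fraction", color = "risk group",
                  title = "Median-split risk groups",
                  subtitle = sprintf("log-rank p = %.3g", ls$p_value)) +
    ggplot2::theme_minimal()
}
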