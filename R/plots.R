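#' Plot a coefficient path
#'
#' Coefficient trajectories against log lambda, one line per SNP that is
#' ever nonzero.
#'
#' @param object a `lambda_path`
#' @param ... unused
#' @return a ggplot object.
#' @export
autoplot.lambda_path <- function(object, ...) {
  tab <- tidy(object)
  if (nrow(tab) == 0)
    return(ggplot2::ggplot() + ggplot2::labs(title = "all coefficients zero"))
  ggplot2::ggplot(tab, ggplot2::aes(x = log(.data$lambda), y = .data$beta,
                                    group = .data$snp_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "log(lambda)", y = "coefficient",
                  title = "Sparse group lasso path") +
    ggplot2::theme_minimal()
}

#' Plot the cross-validation curve
#' @param object a `cv_result`
#' @param ... unused
#' @export
autoplot.cv_result <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = log(.data$lambda),
                                    y = .data$mean_explained_variance)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_explained_variance - .data$sd_explained_variance,
      ymax = .data$mean_explained_variance + .data$sd_explained_variance),
      alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$best_lambda), linetype = 2) +
    ggplot2::labs(x = "log(lambda)", y = "held-out explained variance",
                  title = "Cross-validation") +
    ggplot2::theme_minimal()
}

#' Plot stability-selection frequencies along the genome
#' @param object a `stability_result`
#' @param ... unused
#' @export
autoplot.stability_result <- function(object, ...) {
  tab <- dplyr::mutate(object$table, index = dplyr::row_number())
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$index, y = .data$frequency,
                                    colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "SNP index", y = "selection frequency",
                  title = sprintf("Stability selection (%d resamples)",
                                  object$n_resamples)) +
    ggplot2::theme_minimal()
}

#' Plot a precision-recall curve
#' @param object a `ranking_eval`
#' @param ... unused
#' @export
autoplot.ranking_eval <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall,
                                             y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("PR curve (AUC = %.3f)", object$pr_auc),
                  x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

#' Boxplots of PR-AUC per method over a benchmark grid
#' @param results tibble from [run_benchmark()] (per-dataset rows)
#' @return a ggplot object.
#' @export
plot_benchmark <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data$sigma_sig), y = .data$pr_auc,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~sigma_pop, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sigma_sig", y = "PR-AUC") +
    ggplot2::theme_minimal()
}
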