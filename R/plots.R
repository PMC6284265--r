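# ggplot2 autoplot methods for the result types.

#' Plot a selection result
#'
#' Trajectory statistic against -log10 q-value, selected genes highlighted.
#'
#' @param object a `samgsr_selection`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.samgsr_selection <- function(object, ...) {
  df <- dplyr::filter(object$table, !is.na(.data$samgs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$samgs,
                                   y = -log10(.data$qvalue),
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "trajectory statistic (sum of squared SAM statistics)",
                  y = expression(-log[10]~"q-value"), colour = "selected") +
    ggplot2::theme_minimal()
}

#' Plot a tuning curve
#'
#' Mean cross-validation error across the reduction-cutoff grid, with the
#' chosen cutoff marked.
#'
#' @param object a `samgsr_tuning`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.samgsr_tuning <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(x = .data$cutoff, y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_cutoff, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "reduction cutoff", y = "mean CV misclassification error") +
    ggplot2::theme_minimal()
}

#' Plot a fitted feature table
#'
#' Gene-by-time-point tile map of the final features, filled by the SAM
#' statistic, showing which part of each trajectory drives the association.
#'
#' @param object a `samgsr_fit` or `samgsr_reduction`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.samgsr_fit <- function(object, ...) {
  df <- object$features
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$time_index),
                                   y = .data$gene_id, fill = .data$d_value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  mid = "white", midpoint = 0) +
    ggplot2::labs(x = "time point", y = NULL, fill = "SAM d") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.samgsr_fit
#' @export
autoplot.samgsr_reduction <- function(object, ...) {
  autoplot.samgsr_fit(object, ...)
}

#' Plot averaged posterior probabilities by phenotype
#'
#' @param object a `performance_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.performance_report <- function(object, ...) {
  df <- object$posteriors
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$phenotype),
                                   y = .data$posterior)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.4) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "phenotype (0 = control, 1 = diseased)",
                  y = "averaged posterior P(diseased)") +
    ggplot2::theme_minimal()
}

#' Plot replicate selection frequencies
#'
#' Selection frequency of each causal gene across time points, with the true
#' causal (gene, time) pairs marked.
#'
#' @param object a `samgsr_replicates`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.samgsr_replicates <- function(object, ...) {
  df <- object$freq
  truth <- object$causal_terms
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_index, y = .data$pct,
                                   colour = .data$gene_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(data = dplyr::semi_join(df, truth,
                                                by = c("gene_id", "time_index")),
                        shape = 1, size = 4) +
    ggplot2::labs(x = "time point", y = "selection frequency (%)",
                  colour = "causal gene") +
    ggplot2::theme_minimal()
}
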