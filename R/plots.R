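# ggplot2 diagnostics for the main result types.

#' Plot a gene parameter panel
#'
#' Mean-dispersion scatter on log scales.
#'
#' @param object an [nb_panel()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nb_panel <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$mu, y = .data$phi)) +
    geom_point(alpha = 0.3, size = 0.6) +
    scale_x_log10() +
    scale_y_log10() +
    labs(x = "NB mean μ", y = "NB dispersion φ",
         title = "Gene parameter panel")
}

#' MA plot of a simulated experiment
#'
#' Average log2 expression against log2 fold change of the simulated
#' counts, colored by the true DE status.
#'
#' @param object a `sim_experiment`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sim_experiment <- function(object, ...) {
  y <- sweep(object$counts, 2, normalize_total_count(object$counts), "/")
  m1 <- rowMeans(y[, object$group == 1L, drop = FALSE]) + 0.5
  m2 <- rowMeans(y[, object$group == 2L, drop = FALSE]) + 0.5
  df <- tibble(
    a = 0.5 * (log2(m1) + log2(m2)),
    m = log2(m2) - log2(m1),
    status = factor(object$truth$d, levels = c(-1, 0, 1),
                    labels = c("down", "null", "up"))
  )
  ggplot(df, aes(x = .data$a, y = .data$m, color = .data$status)) +
    geom_point(alpha = 0.4, size = 0.6) +
    labs(x = "Average log2 expression", y = "log2 fold change",
         color = "truth", title = "Simulated experiment")
}

#' Plot benchmark metrics
#'
#' Mean FPR and TPR per method and FDR cutoff, plus mean AUC.
#'
#' @param object a `de_benchmark`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.de_benchmark <- function(object, ...) {
  df <- object$metric_means |>
    tidyr::pivot_longer(c("fpr", "tpr"), names_to = "metric",
                        values_to = "value")
  ggplot(df, aes(x = .data$method, y = .data$value,
                 fill = factor(.data$cutoff))) +
    geom_col(position = "dodge") +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "rate", fill = "FDR cutoff",
         title = sprintf("Scenario %s: mean rates over %d datasets",
                         object$config$name, object$config$n_datasets)) +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Heatmap of cross-method fold-change concordance
#'
#' @param object a `concordance_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.concordance_report <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$method_a, y = .data$method_b,
                 fill = .data$spearman_fc)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$spearman_fc)), size = 3) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "Spearman",
         title = "Fold-change concordance") +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
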