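#' Plot batch-mixing metrics for candidate embeddings
#'
#' Bar panel per metric, embeddings ordered by aggregate rank (best first).
#'
#' @param report the tibble from [rank_integrations()].
#' @return a ggplot.
#' @export
plot_integration_metrics <- function(report) {
  long <- report %>%
    pivot_longer(c("batch_asw_score", "kbet_acceptance", "ilisi_mean"),
                 names_to = "metric", values_to = "value") %>%
    mutate(embedding = stats::reorder(.data$embedding, .data$aggregate_rank))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$embedding, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Batch-mixing metrics (higher = better mixed)") +
    ggplot2::theme_minimal()
}

#' Forest plot of differential abundance
#'
#' @param object a `da_result` from [differential_abundance()].
#' @param q_cutoff highlight types below this BH q.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot da_result
#' @export
autoplot.da_result <- function(object, q_cutoff = 0.05, ...) {
  d <- tibble::as_tibble(object) %>%
    mutate(sig = .data$q < q_cutoff,
           cell_type = stats::reorder(.data$cell_type, .data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$cell_type,
                                  color = .data$sig)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "grey40"),
                                name = sprintf("q < %.2g", q_cutoff)) +
    ggplot2::labs(x = "CLR coefficient", y = NULL) +
    ggplot2::theme_minimal()
}

#' Diversity-by-phenotype boxplot
#'
#' @param diversity the tibble from [ctds()].
#' @param by covariate column to group by (e.g. `"grade"`, `"subtype"`).
#' @return a ggplot.
#' @export
plot_ctds <- function(diversity, by = "grade") {
  stopifnot(by %in% names(diversity))
  ggplot2::ggplot(diversity,
                  ggplot2::aes(x = factor(.data[[by]]), y = .data$ctds)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~compartment) +
    ggplot2::labs(x = by, y = "cell-type diversity (CTDS)") +
    ggplot2::theme_minimal()
}

#' Hazard-ratio forest plot of the clade survival scan
#'
#' @param scan the list from [node_survival_scan()].
#' @return a ggplot.
#' @export
plot_survival_scan <- function(scan) {
  d <- scan$results %>%
    mutate(label = sprintf("node %d/%s", .data$node_id, .data$clade))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$label,
                                  color = .data$call, shape = .data$cohort)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_color_manual(values = c(advantage = "forestgreen",
                                           disadvantage = "firebrick",
                                           ns = "grey50")) +
    ggplot2::labs(x = "hazard ratio per SD of clade score", y = NULL) +
    ggplot2::theme_minimal()
}
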