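# ggplot2 views of the result objects. Tables are the contract; the plots
# are convenience artifacts.

#' @method autoplot diff_ess
#' @export
autoplot.diff_ess <- function(object, ...) {
  df <- object$results[object$results$testable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff,
                                   y = -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean CERES difference (group A - group B)",
                  y = expression(-log[10] ~ p),
                  colour = paste0("p < ", object$params$alpha),
                  title = "Differential essentiality") +
    ggplot2::theme_minimal()
}

#' @method autoplot nb_de
#' @export
autoplot.nb_de <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(pmax(.data$padj, 1e-300)),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = -log10(object$params$alpha),
                        linetype = "dashed") +
    ggplot2::labs(x = paste0("log2 fold change (",
                             object$params$condition_levels[2], " vs ",
                             object$params$condition_levels[1], ")"),
                  y = expression(-log[10] ~ p[adj]),
                  colour = paste0("padj < ", object$params$alpha),
                  title = "Differential expression") +
    ggplot2::theme_minimal()
}

#' @method autoplot pair_screen
#' @export
autoplot.pair_screen <- function(object, ...) {
  df <- object$results[object$results$testable, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chi2, y = -log10(.data$p),
                                   colour = .data$driver_group,
                                   shape = .data$self_pair)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = expression(chi^2), y = expression(-log[10] ~ p),
                  title = "Mutation x essentiality association screen") +
    ggplot2::theme_minimal()
}

#' @method autoplot pair_followup
#' @export
autoplot.pair_followup <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohens_d, y = -log10(.data$mw_p),
                                   colour = .data$driver_group,
                                   shape = .data$self_pair)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::labs(x = "Cohen's d (mutant vs wildtype CERES)",
                  y = expression(-log[10] ~ p),
                  title = "Effect-size follow-up of significant pairs") +
    ggplot2::theme_minimal()
}

#' @method autoplot target_nomination
#' @export
autoplot.target_nomination <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = .data$total_membrane_score,
                                   colour = .data$nominated)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_hline(yintercept = object$params$min_score,
                        linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change (malignant vs benign)",
                  y = "plasma-membrane confidence score",
                  title = "Surface-target nomination") +
    ggplot2::theme_minimal()
}

#' Mean-essentiality scatter against the y = x diagonal
#'
#' @param means Tibble from [mean_essentiality_by_group()] with exactly
#'   two group-mean columns.
#' @return A ggplot.
#' @export
plot_mean_essentiality <- function(means) {
  cols <- names(means)[startsWith(names(means), "mean_")]
  stopifnot(length(cols) == 2)
  ggplot2::ggplot(means, ggplot2::aes(x = .data[[cols[2]]],
                                      y = .data[[cols[1]]])) +
    ggplot2::geom_point(alpha = 0.4, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = sub("mean_", "mean CERES, ", cols[2]),
                  y = sub("mean_", "mean CERES, ", cols[1]),
                  title = "Group mean essentiality") +
    ggplot2::theme_minimal()
}

#' Heat-map view of a stratified-essentiality workflow
#'
#' @param wf A `condep_workflow` from [wf_strata_heatmap()].
#' @return A ggplot.
#' @export
plot_strata_heatmap <- function(wf) {
  stopifnot(inherits(wf, "condep_workflow"), wf$workflow == "strata_heatmap")
  df <- wf$tables$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$line_id, y = .data$gene,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "CERES",
                  title = "Gene essentiality by stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
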