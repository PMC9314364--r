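#' Plot an evaluation report
#'
#' Out-of-sample R-squared per outcome, one bar per representation, with the
#' per-model mean as a dashed reference line.
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot evaluation_report
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$outcome, y = .data$r2,
                               fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(data = object$aggregate,
                        ggplot2::aes(yintercept = .data$mean_r2,
                                     colour = .data$model),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = expression("out-of-sample" ~ R^2),
                  fill = "representation") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a divergence report
#'
#' Distributions of the per-participant cosine similarities: within each
#' representation across the two administrations, and between the two
#' representations.
#'
#' @param object A `divergence_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot divergence_report
#' @export
autoplot.divergence_report <- function(object, ...) {
  ggplot2::ggplot(object$similarities,
                  ggplot2::aes(x = .data$similarity, fill = .data$component)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "cosine similarity", y = "density", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a correlation report as a heatmap
#'
#' @param object A `correlation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot correlation_report
#' @export
autoplot.correlation_report <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(rownames(object), ncol(object)),
    col = rep(colnames(object), each = nrow(object)),
    r = as.vector(unclass(object)))
  df$row <- factor(df$row, levels = rev(rownames(object)))
  df$col <- factor(df$col, levels = colnames(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                                  mid = "white", high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
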