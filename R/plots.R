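# ggplot2 views of the main result types.

#' Plot cross-validation fold scores
#'
#' One panel per matching mode, folds on the x axis, bars per system.
#'
#' @param object A `resner_cv`.
#' @param metric Which score to plot: `"f_score"`, `"precision"` or
#'   `"recall"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.resner_cv <- function(object, metric = c("f_score", "precision", "recall"),
                               ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data[[metric]],
                               fill = .data$system)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$mode)) +
    ggplot2::labs(x = "fold", y = paste(metric, "(%)"),
                  title = "Cross-validated mention-level scores") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot top stemmed-token frequencies within resource names
#'
#' @param freq Tibble from [stem_token_frequency()].
#' @param top_n Number of stems shown.
#' @return A ggplot object.
#' @export
plot_stem_frequency <- function(freq, top_n = 20L) {
  top <- utils::head(freq, top_n)
  ggplot2::ggplot(top, ggplot2::aes(x = stats::reorder(.data$stem, .data$count),
                                    y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Most frequent stemmed tokens in resource names") +
    ggplot2::theme_minimal()
}

#' Plot the POS-pattern profile of mention structure
#'
#' @param profile Tibble from [pos_pattern_profile()].
#' @param top_n Patterns shown individually; the rest are pooled as
#'   "other".
#' @return A ggplot object.
#' @export
plot_pos_patterns <- function(profile, top_n = 6L) {
  top <- utils::head(profile, top_n)
  rest <- sum(profile$percentage) - sum(top$percentage)
  df <- dplyr::bind_rows(top[, c("pattern", "percentage")],
                         tibble::tibble(pattern = "other", percentage = rest))
  df$pattern <- factor(df$pattern, levels = rev(df$pattern))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pattern, y = .data$percentage)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "% of patterns",
                  title = "POS structure of resource names") +
    ggplot2::theme_minimal()
}
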