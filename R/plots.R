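#' Plot a conservation summary
#'
#' Bar chart of the conserved fraction per group (tier or trait category)
#' with the genome-wide baseline drawn as a dashed reference line.
#'
#' @param object A `gwasfly_conservation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwasfly_conservation
#' @export
autoplot.gwasfly_conservation <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- if ("tier" %in% names(df)) df$tier else df$group
  df <- df[!is.na(df$fraction), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$fraction),
                                   y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = df$baseline_fraction[1], linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "candidate genes conserved in fly",
                  caption = "dashed line: genome-wide baseline") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot an expression-profile summary
#'
#' Grouped bars of the fraction of homolog profiles expressed per tissue,
#' by candidate category, with the pooled-candidate and all-fly-genes
#' reference rows alongside.
#'
#' @param object A `gwasfly_expression` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwasfly_expression
#' @export
autoplot.gwasfly_expression <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$fraction), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$fraction,
                                   fill = .data$tissue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "homologs expressed (RPKM threshold)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a phenotype/essentiality summary
#'
#' Bars of the lethal, neuronal, and any-annotation fractions per category.
#'
#' @param object A `gwasfly_phenotype` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gwasfly_phenotype
#' @export
autoplot.gwasfly_phenotype <- function(object, ...) {
  df <- as_tibble(object)
  long <- tidyr::pivot_longer(df, c("frac_lethal", "frac_neuronal", "frac_annotated"),
                              names_to = "class", values_to = "fraction")
  long$class <- sub("^frac_", "", long$class)
  long <- long[!is.na(long$fraction), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$fraction,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "fraction of homolog profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the tier-level conservation of a study
#'
#' @param x A `gwasfly_study`.
#' @param y Unused.
#' @param ... Unused.
#' @return `x`, invisibly; the tier conservation bar chart is printed.
#' @export
plot.gwasfly_study <- function(x, y, ...) {
  print(autoplot(x$by_tier))
  invisible(x)
}
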