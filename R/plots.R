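# ggplot2 displays for the result tables.

#' Volcano plot annotated by seed-match status
#'
#' Significant genes (the `down`/`up` classes) are coloured; seed-matched
#' genes are drawn as triangles on top so the seed-driven tail of the
#' downregulated arm is visible.
#'
#' @param object A `seed_volcano` tibble from [volcano_export()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot seed_volcano
#' @export
autoplot.seed_volcano <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$log2FC, y = .data$neg_log10_padj)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class,
                                     shape = .data$has_match),
                        alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(down = "#2166ac", up = "#b2182b",
                                            unchanged = "grey60",
                                            excluded = "grey85")) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "seed match") +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ "adjusted p"),
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.seed_volcano
#' @param volcano A `seed_volcano` tibble.
#' @export
plot_volcano <- function(volcano, ...) autoplot.seed_volcano(volcano, ...)

#' Bar chart of enrichment significance per panel
#'
#' One bar per (seed window, direction) panel showing -log10 of the
#' one-sided Fisher p; the dashed line marks p = 0.05.
#'
#' @param object A `seed_enrichment` tibble from [run_enrichment()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot seed_enrichment
#' @export
autoplot.seed_enrichment <- function(object, ...) {
  dat <- mutate(as_tibble(object),
                panel = paste(.data$spec_label, .data$direction, sep = " / "),
                neg_log10_p = -log10(pmax(.data$p_one_sided,
                                          .Machine$double.xmin)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$panel, y = .data$neg_log10_p,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "Fisher p (one-sided)")) +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.seed_enrichment
#' @param enrichment A `seed_enrichment` tibble.
#' @export
plot_enrichment <- function(enrichment, ...) autoplot.seed_enrichment(enrichment, ...)
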