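# ggplot2 views of the main result types.

ORIGIN_FILLS <- c(Host = "#d95f02", Microbiota = "#1b9e77",
                  `Co-Metabolism` = "#7570b3", Food = "#e7298a",
                  Drug = "#66a61e", Environment = "#e6ab02",
                  Others = "#a6761d", Unknown = "#999999")

#' Bar plot of metabolite origin categories
#'
#' @param object an `origin_calls` tibble from [classify_origins()].
#' @param collapse_others collapse Food/Drug/Environment into "Others".
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot origin_calls
#' @export
autoplot.origin_calls <- function(object, collapse_others = FALSE, ...) {
  counts <- category_counts(object, collapse_others = collapse_others)
  counts$category <- factor(counts$category, levels = counts$category)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = ORIGIN_FILLS) +
    ggplot2::labs(x = NULL, y = "metabolites",
                  title = "Metabolite origin categories") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' Pathways ordered by significance; dot size is the hit count `q`, the
#' dashed line marks the significance level used for the flags.
#'
#' @param object an [run_mpea()] result.
#' @param top plot at most this many pathways.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot mpea_result
#' @export
autoplot.mpea_result <- function(object, top = 20, ...) {
  df <- utils::head(tidy(object), top)
  df$name <- factor(df$name, levels = rev(df$name))
  alpha <- attr(object, "alpha") %||% 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value),
                                   y = .data$name,
                                   size = .data$q,
                                   color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`TRUE` = "#c00000",
                                           `FALSE` = "#999999")) +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL,
                  title = paste("Pathway enrichment -",
                                attr(object, "scope"), "scope")) +
    ggplot2::theme_minimal()
}

#' Correlation heatmap
#'
#' @param object a [correlate()] result.
#' @param ... unused.
#' @return a ggplot tile map of coefficients, significant pairs starred.
#' @method autoplot correlation_table
#' @export
autoplot.correlation_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$star <- ifelse(df$significant, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$taxon,
                                   fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$star), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#008000", mid = "white",
                                  high = "#c00000", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Taxon-metabolite correlation (",
                                 df$method[1], ", ", df$rank[1], ")")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Sankey band diagram
#'
#' A static rendering of a reaction Sankey graph: columns left to right
#' (metabolites, enzymes, then phylum through species), band thickness
#' proportional to the distinct-species width, gray background bands and
#' red/green positive/negative correlation bands (dark when emphasized).
#'
#' @param object a `sankey_graph`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot sankey_graph
#' @export
autoplot.sankey_graph <- function(object, ...) {
  nodes <- object$nodes
  nodes <- nodes |>
    dplyr::group_by(.data$column) |>
    dplyr::mutate(y = rev(seq_len(dplyr::n()))) |>
    dplyr::ungroup()
  links <- tidy(object)
  pos <- stats::setNames(nodes$y, nodes$node_id)
  colx <- stats::setNames(nodes$column, nodes$node_id)
  links$x <- unname(colx[links$source])
  links$xend <- unname(colx[links$target])
  links$y <- unname(pos[links$source])
  links$yend <- unname(pos[links$target])
  links$color <- ifelse(links$emphasized,
                        LINK_COLORS_DARK[links$color_class],
                        LINK_COLORS[links$color_class])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = links,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, linewidth = .data$width),
      color = links$color, alpha = 0.8) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$column, y = .data$y),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$column, y = .data$y,
                                    label = .data$label),
                       size = 2.6, vjust = -1) +
    ggplot2::scale_linewidth(range = c(0.3, 4)) +
    ggplot2::scale_x_continuous(
      breaks = unname(SANKEY_COLUMNS),
      labels = names(SANKEY_COLUMNS)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste(toupper(object$variant), "Sankey -",
                                object$reaction_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
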