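# Serialization of Sankey graphs and summary networks: a documented JSON
# schema (lossless, byte-stable round trip), GraphML via igraph, and a
# dependency-free standalone HTML/SVG rendering.

#' Export a network to JSON, GraphML or HTML
#'
#' * `json`: the package's network schema — an object with `type`
#'   (`"sankey_graph"` or `"summary_network"`), the graph metadata, and
#'   column-oriented `nodes` and `links`/`edges` tables. Export ->
#'   [import_network()] -> export is byte-identical.
#' * `graphml`: nodes with kind/label/regulation(/column/shape)
#'   attributes, links with width/color/emphasis (via [igraph]).
#' * `html`: a self-contained SVG rendering of the layout — columns left
#'   to right, band thickness proportional to width, gray background
#'   links, red/green positive/negative links (dark when emphasized).
#'
#' @param graph a `sankey_graph` or `summary_network`.
#' @param path output file.
#' @param format `"json"`, `"graphml"` or `"html"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(graph, path, format = c("json", "graphml",
                                                   "html")) {
  format <- match.arg(format)
  switch(format,
         json = export_network_json(graph, path),
         graphml = export_network_graphml(graph, path),
         html = export_network_html(graph, path))
  invisible(path)
}

network_payload <- function(graph) {
  if (inherits(graph, "sankey_graph")) {
    list(type = "sankey_graph",
         reaction_id = graph$reaction_id,
         variant = graph$variant,
         nodes = as.list(graph$nodes),
         links = as.list(graph$links))
  } else if (inherits(graph, "summary_network")) {
    list(type = "summary_network",
         origin = graph$origin,
         p_threshold = graph$p_threshold,
         nodes = as.list(graph$nodes),
         edges = as.list(graph$edges))
  } else stop_input("unsupported graph class")
}

export_network_json <- function(graph, path) {
  jsonlite::write_json(network_payload(graph), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

#' Import a network from its JSON export
#'
#' @param path file written by [export_network()] with `format = "json"`.
#' @return the reconstructed `sankey_graph` or `summary_network`.
#' @export
import_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_cols <- function(l, int_cols = character(0),
                      lgl_cols = character(0), dbl_cols = character(0)) {
    out <- tibble::as_tibble(lapply(l, function(v) {
      v <- unlist(v)
      if (is.null(v)) character(0) else v
    }))
    for (cc in intersect(int_cols, names(out)))
      out[[cc]] <- as.integer(out[[cc]])
    for (cc in intersect(lgl_cols, names(out)))
      out[[cc]] <- as.logical(out[[cc]])
    for (cc in intersect(dbl_cols, names(out)))
      out[[cc]] <- as.numeric(out[[cc]])
    out
  }
  if (identical(x$type, "sankey_graph")) {
    new_sankey_graph(x$reaction_id, x$variant,
                     as_cols(x$nodes, int_cols = "column"),
                     as_cols(x$links, int_cols = "width",
                             lgl_cols = "emphasized"))
  } else if (identical(x$type, "summary_network")) {
    structure(list(origin = x$origin, p_threshold = x$p_threshold,
                   nodes = as_cols(x$nodes),
                   edges = as_cols(x$edges,
                                   dbl_cols = c("coefficient", "p_value"))),
              class = "summary_network")
  } else stop_input("not a recognized network JSON file: ", path)
}

network_igraph <- function(graph) {
  if (inherits(graph, "sankey_graph")) {
    nodes <- graph$nodes
    links <- graph$links
    igraph::graph_from_data_frame(
      d = data.frame(from = links$source, to = links$target,
                     width = links$width, color_class = links$color_class,
                     emphasized = as.integer(links$emphasized)),
      directed = TRUE,
      vertices = data.frame(name = nodes$node_id, kind = nodes$kind,
                            label = nodes$label,
                            regulation = nodes$regulation,
                            column = nodes$column))
  } else {
    nodes <- graph$nodes
    edges <- graph$edges
    igraph::graph_from_data_frame(
      d = data.frame(from = edges$taxon, to = edges$metabolite,
                     coefficient = edges$coefficient,
                     p_value = edges$p_value, sign = edges$sign),
      directed = FALSE,
      vertices = data.frame(name = nodes$node_id, kind = nodes$kind,
                            shape = nodes$shape, label = nodes$label,
                            regulation = nodes$regulation))
  }
}

export_network_graphml <- function(graph, path) {
  igraph::write_graph(network_igraph(graph), path, format = "graphml")
}

LINK_COLORS <- c(background = "#bbbbbb", positive = "#e08080",
                 negative = "#80c080")
LINK_COLORS_DARK <- c(background = "#bbbbbb", positive = "#c00000",
                      negative = "#008000")
NODE_COLORS <- c(up = "#c00000", down = "#008000", none = "#666699")

export_network_html <- function(graph, path) {
  if (inherits(graph, "summary_network")) {
    nodes <- graph$nodes
    nodes$column <- ifelse(nodes$kind == "metabolite", 1L, 2L)
    links <- tibble::tibble(source = graph$edges$taxon,
                            target = graph$edges$metabolite,
                            width = 1L,
                            color_class = graph$edges$sign,
                            emphasized = FALSE)
    title <- paste("Summary network -", graph$origin)
  } else {
    nodes <- graph$nodes
    links <- graph$links
    title <- paste(toupper(graph$variant), "Sankey -", graph$reaction_id)
  }
  w <- 960
  h <- max(320, 28 * max(table(nodes$column)))
  cols <- sort(unique(nodes$column))
  x_of <- stats::setNames(
    seq(80, w - 80, length.out = max(2, length(cols))), cols)
  nodes <- nodes |>
    dplyr::group_by(.data$column) |>
    dplyr::mutate(y = seq(40, h - 40,
                          length.out = max(2, dplyr::n()))[
                            seq_len(dplyr::n())]) |>
    dplyr::ungroup()
  nx <- stats::setNames(unname(x_of[as.character(nodes$column)]),
                        nodes$node_id)
  ny <- stats::setNames(nodes$y, nodes$node_id)
  paths <- if (nrow(links) > 0) {
    color <- ifelse(links$emphasized,
                    LINK_COLORS_DARK[links$color_class],
                    LINK_COLORS[links$color_class])
    x1 <- nx[links$source] + 6
    x2 <- nx[links$target] - 6
    y1 <- ny[links$source]
    y2 <- ny[links$target]
    sprintf(paste0('<path d="M %.1f %.1f C %.1f %.1f, %.1f %.1f, %.1f ',
                   '%.1f" stroke="%s" stroke-width="%d" fill="none" ',
                   'opacity="0.7"/>'),
            x1, y1, (x1 + x2) / 2, y1, (x1 + x2) / 2, y2, x2, y2,
            color, pmin(2L + 2L * links$width, 14L))
  } else character(0)
  node_fill <- NODE_COLORS[ifelse(nodes$regulation %in% names(NODE_COLORS),
                                  nodes$regulation, "none")]
  shapes <- sprintf(
    paste0('<circle cx="%.1f" cy="%.1f" r="5" fill="%s"/>',
           '<text x="%.1f" y="%.1f" font-size="10" ',
           'font-family="sans-serif">%s</text>'),
    nx[nodes$node_id], nodes$y, node_fill,
    nx[nodes$node_id] + 8, nodes$y + 3, htmlesc(nodes$label))
  html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\"/>",
            paste0("<title>", htmlesc(title), "</title></head><body>"),
            paste0("<h3>", htmlesc(title), "</h3>"),
            sprintf('<svg width="%d" height="%d">', w, round(h)),
            paths, shapes, "</svg></body></html>")
  writeLines(html, path)
}

htmlesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
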