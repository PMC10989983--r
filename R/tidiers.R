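# broom-style tidiers so every result type drops cleanly into a
# dplyr/ggplot2 workflow.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an enrichment result
#'
#' @param x an [run_mpea()] result.
#' @param ... unused.
#' @return a plain tibble of the per-pathway rows.
#' @method tidy mpea_result
#' @export
tidy.mpea_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "scope") <- NULL
  attr(out, "k") <- NULL
  attr(out, "universe_size") <- NULL
  attr(out, "unmapped") <- NULL
  attr(out, "alpha") <- NULL
  out
}

#' @rdname tidy.mpea_result
#' @method glance mpea_result
#' @export
glance.mpea_result <- function(x, ...) {
  tibble::tibble(scope = attr(x, "scope"),
                 k = attr(x, "k"),
                 universe_size = attr(x, "universe_size"),
                 n_unmapped = length(attr(x, "unmapped")),
                 n_pathways = nrow(x),
                 n_significant = sum(x$significant))
}

#' Tidy a Sankey graph into a link table
#'
#' @param x a `sankey_graph`.
#' @param ... unused.
#' @return tibble of links with source/target kind and label resolved.
#' @method tidy sankey_graph
#' @export
tidy.sankey_graph <- function(x, ...) {
  nd <- x$nodes
  x$links |>
    dplyr::left_join(rlang::set_names(
      nd[, c("node_id", "kind", "label")],
      c("source", "source_kind", "source_label")), by = "source") |>
    dplyr::left_join(rlang::set_names(
      nd[, c("node_id", "kind", "label")],
      c("target", "target_kind", "target_label")), by = "target")
}

#' @rdname tidy.sankey_graph
#' @method glance sankey_graph
#' @export
glance.sankey_graph <- function(x, ...) {
  species_nodes <- sum(x$nodes$kind == "species")
  tibble::tibble(reaction_id = x$reaction_id, variant = x$variant,
                 n_nodes = nrow(x$nodes), n_links = nrow(x$links),
                 n_species = species_nodes,
                 n_emphasized = sum(x$links$emphasized))
}

#' Tidy a summary network into an edge table
#'
#' @param x a `summary_network`.
#' @param ... unused.
#' @return tibble of taxon-metabolite edges with node labels resolved.
#' @method tidy summary_network
#' @export
tidy.summary_network <- function(x, ...) {
  lab <- stats::setNames(x$nodes$label, x$nodes$node_id)
  out <- x$edges
  out$taxon_label <- unname(lab[out$taxon])
  out$metabolite_label <- unname(lab[out$metabolite])
  out
}

#' @rdname tidy.summary_network
#' @method glance summary_network
#' @export
glance.summary_network <- function(x, ...) {
  tibble::tibble(origin = x$origin, p_threshold = x$p_threshold,
                 n_metabolites = sum(x$nodes$kind == "metabolite"),
                 n_taxa = sum(x$nodes$kind == "taxon"),
                 n_edges = nrow(x$edges))
}
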