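#' Per-origin summary network of metabolites and taxa
#'
#' Integrates one origin's evidence into a single bipartite picture: the
#' metabolite nodes are the differential metabolites belonging to the
#' origin's significant pathways (drawn as diamonds, colored by up/down
#' regulation), the taxon nodes are drawn as dots, and a taxon-metabolite
#' edge is included iff the correlation p-value is at or below
#' `p_threshold` (default 0.01), colored by the correlation sign.
#' Host-origin networks contain metabolite nodes only, since host-specific
#' metabolites have no microbial partner by definition.
#'
#' @param origin `"host"`, `"microbiota"` or `"cometabolism"`.
#' @param mpea an [run_mpea()] result for that origin's scope; its
#'   significant pathways define the metabolite set.
#' @param diff_metab [differential_analysis()] result carrying `entry_id`s
#'   for the metabolites (regulation colors).
#' @param correlations a [correlate()] result (taxa vs metabolites).
#' @param kb the [metab_kb()] of the run.
#' @param diff_taxa optional differential result for taxa at the
#'   correlation rank (taxon regulation colors).
#' @param p_threshold correlation p-value cutoff for edges.
#' @return object of class `summary_network`: list with `origin`,
#'   `p_threshold`, `nodes` (tibble `node_id`, `kind`, `shape`, `label`,
#'   `regulation`) and `edges` (tibble `taxon`, `metabolite`,
#'   `coefficient`, `p_value`, `sign`).
#' @export
build_summary_network <- function(origin, mpea, diff_metab, correlations,
                                  kb, diff_taxa = NULL, p_threshold = 0.01) {
  origin <- match.arg(origin, c("host", "microbiota", "cometabolism"))
  stopifnot(inherits(kb, "metab_kb"))
  sig_pw <- mpea$pathway_id[mpea$significant]
  pw_members <- unique(kb$pathway_members$entry_id[
    kb$pathway_members$pathway_id %in% sig_pw])
  dm <- tibble::as_tibble(diff_metab)
  if (!"entry_id" %in% names(dm))
    stop_input("diff_metab needs an entry_id column (see run_dmoa)")
  dm <- dm[dm$significant & !is.na(dm$entry_id) &
             dm$entry_id %in% pw_members, ]
  labels <- kb$entries$name[match(dm$entry_id, kb$entries$entry_id)]
  labels <- ifelse(is.na(labels) | labels == "", dm$entry_id, labels)
  met_nodes <- tibble::tibble(
    node_id = paste0("metabolite:", dm$entry_id),
    kind = "metabolite", shape = "diamond", label = labels,
    regulation = dm$direction)

  edges <- tibble::tibble(taxon = character(), metabolite = character(),
                          coefficient = numeric(), p_value = numeric(),
                          sign = character())
  taxon_nodes <- NULL
  if (origin != "host" && nrow(dm) > 0 && !is.null(correlations)) {
    cr <- tibble::as_tibble(correlations)
    ids <- kb$entries$entry_id
    nms <- normalize_name(kb$entries$name)
    cr$entry_id <- dplyr::coalesce(
      ids[match(cr$metabolite, ids)],
      ids[match(normalize_name(cr$metabolite), nms)])
    cr <- cr[!is.na(cr$entry_id) & cr$entry_id %in% dm$entry_id &
               cr$p_value <= p_threshold & !cr$degenerate, ]
    if (nrow(cr) > 0) {
      edges <- tibble::tibble(
        taxon = cr$taxon,
        metabolite = paste0("metabolite:", cr$entry_id),
        coefficient = cr$coefficient,
        p_value = cr$p_value,
        sign = ifelse(cr$coefficient >= 0, "positive", "negative"))
      taxa <- unique(cr$taxon)
      reg <- rep("none", length(taxa))
      if (!is.null(diff_taxa)) {
        dt <- tibble::as_tibble(diff_taxa)
        hit <- match(taxa, dt$feature_id)
        reg <- ifelse(!is.na(hit) & dt$significant[hit],
                      dt$direction[hit], "none")
      }
      lab <- vapply(strsplit(taxa, "[|;]"), function(p)
        sub("^[pcofgs]__", "", p[length(p)]), character(1))
      taxon_nodes <- tibble::tibble(
        node_id = taxa, kind = "taxon", shape = "dot",
        label = lab, regulation = reg)
      edges$taxon <- edges$taxon
    }
  }
  nodes <- dplyr::bind_rows(met_nodes, taxon_nodes)
  if (nrow(edges) > 0) {
    stopifnot(all(edges$taxon %in% nodes$node_id),
              all(edges$metabolite %in% nodes$node_id))
  }
  structure(list(origin = origin, p_threshold = p_threshold,
                 nodes = nodes, edges = edges),
            class = "summary_network")
}

#' @export
print.summary_network <- function(x, ...) {
  cat("<summary_network>", x$origin, "origin -", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges (p <=", x$p_threshold, ")\n")
  invisible(x)
}
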