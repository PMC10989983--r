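# Reaction-centric Sankey networks linking metabolites, enzymes and
# bacterial taxonomy.

SANKEY_COLUMNS <- c(metabolite = 1L, enzyme = 2L, phylum = 3L, class = 4L,
                    order = 5L, family = 6L, genus = 7L, species = 8L)

#' Reactions of a pathway touched by differential metabolites
#'
#' @param pathway_id pathway identifier present in the knowledge base.
#' @param diff_ids character vector of differential metabolite entry ids.
#' @param kb a [metab_kb()].
#' @return tibble `reaction_id`, `substrates`, `products`, `enzymes`
#'   (`;`-joined), `n_organisms` — one row per reaction of the pathway
#'   whose substrates or products intersect `diff_ids`, in stable
#'   reaction-id order.
#' @export
reactions_for_pathway <- function(pathway_id, diff_ids, kb) {
  stopifnot(inherits(kb, "metab_kb"))
  if (!pathway_id %in% kb$pathways$pathway_id)
    stop_input("unknown pathway: ", pathway_id)
  rxn_ids <- kb$reaction_pathways$reaction_id[
    kb$reaction_pathways$pathway_id == pathway_id]
  touched <- kb$reaction_participants |>
    dplyr::filter(.data$reaction_id %in% rxn_ids,
                  .data$entry_id %in% diff_ids) |>
    dplyr::pull("reaction_id") |>
    unique()
  parts <- kb$reaction_participants |>
    dplyr::filter(.data$reaction_id %in% touched)
  enz <- kb$reaction_enzymes |>
    dplyr::filter(.data$reaction_id %in% touched)
  orgs <- kb$reaction_organisms |>
    dplyr::filter(.data$reaction_id %in% touched)
  tibble::tibble(reaction_id = sort(unique(touched))) |>
    dplyr::mutate(
      substrates = purrr::map_chr(.data$reaction_id, \(r) join_set(list(
        parts$entry_id[parts$reaction_id == r & parts$role == "substrate"]))),
      products = purrr::map_chr(.data$reaction_id, \(r) join_set(list(
        parts$entry_id[parts$reaction_id == r & parts$role == "product"]))),
      enzymes = purrr::map_chr(.data$reaction_id, \(r) join_set(list(
        enz$ec_number[enz$reaction_id == r]))),
      n_organisms = purrr::map_int(.data$reaction_id, \(r)
        dplyr::n_distinct(orgs$org_code[orgs$reaction_id == r])))
}

new_sankey_graph <- function(reaction_id, variant, nodes, links) {
  nodes <- tibble::as_tibble(nodes)
  links <- tibble::as_tibble(links)
  if (nrow(links) > 0) {
    col_of <- stats::setNames(nodes$column, nodes$node_id)
    stopifnot(all(links$source %in% nodes$node_id),
              all(links$target %in% nodes$node_id),
              all(col_of[links$target] - col_of[links$source] == 1L),
              all(links$width >= 1L),
              all(!links$emphasized | links$color_class != "background"))
    links$width <- as.integer(links$width)
  }
  # deterministic layout: within a column, heaviest nodes first
  w <- rep(0, nrow(nodes))
  if (nrow(links) > 0) {
    weight_in <- tapply(links$width, links$target, sum)
    weight_out <- tapply(links$width, links$source, sum)
    wi <- weight_in[nodes$node_id]
    wo <- weight_out[nodes$node_id]
    w <- pmax(ifelse(is.na(wi), 0, wi), ifelse(is.na(wo), 0, wo))
  }
  nodes <- nodes[order(nodes$column, -w, nodes$label, method = "radix"), ]
  structure(list(reaction_id = reaction_id, variant = variant,
                 nodes = nodes, links = links),
            class = "sankey_graph")
}

#' @export
print.sankey_graph <- function(x, ...) {
  cat("<sankey_graph>", x$variant, "variant for", x$reaction_id, "-",
      nrow(x$nodes), "nodes,", nrow(x$links), "links\n")
  invisible(x)
}

# Gather everything about one reaction needed by the builders.
reaction_context <- function(kb, reaction_id) {
  if (!reaction_id %in% kb$reactions$reaction_id)
    stop_input("unknown reaction: ", reaction_id)
  parts <- kb$reaction_participants |>
    dplyr::filter(.data$reaction_id == !!reaction_id) |>
    dplyr::left_join(kb$entries[, c("entry_id", "name")], by = "entry_id") |>
    dplyr::mutate(label = ifelse(.data$name == "", .data$entry_id,
                                 .data$name))
  enzymes <- sort(unique(kb$reaction_enzymes$ec_number[
    kb$reaction_enzymes$reaction_id == reaction_id]))
  orgs <- kb$reaction_organisms |>
    dplyr::filter(.data$reaction_id == !!reaction_id) |>
    dplyr::left_join(kb$organisms, by = "org_code")
  # taxonomy columns only make sense for organisms with a lineage
  # (microbes); hosts/other organisms without one are left out of the fan
  complete <- rowSums(orgs[, TAXONOMY_RANKS, drop = FALSE] == "" |
                        is.na(orgs[, TAXONOMY_RANKS, drop = FALSE])) == 0
  orgs <- orgs[complete, , drop = FALSE]
  list(parts = parts, enzymes = enzymes, orgs = orgs)
}

node_id_of <- function(kind, label) paste0(kind, ":", label)

# Taxonomy chain links from a lineage table with one row per leaf.
# `leaf` identifies the distinct unit being counted (species / finest-rank
# taxon); widths are distinct-leaf counts beneath each branch.
lineage_links <- function(lin, leaf, finest = "species") {
  ranks <- TAXONOMY_RANKS[seq_len(match(finest, TAXONOMY_RANKS))]
  if (length(ranks) < 2) return(NULL)
  purrr::map(seq_len(length(ranks) - 1), function(i) {
    up <- ranks[i]
    dn <- ranks[i + 1]
    tibble::tibble(src_kind = up, src_label = lin[[up]],
                   dst_kind = dn, dst_label = lin[[dn]], leaf = leaf) |>
      dplyr::group_by(.data$src_kind, .data$src_label,
                      .data$dst_kind, .data$dst_label) |>
      dplyr::summarise(width = dplyr::n_distinct(.data$leaf),
                       leaves = list(unique(.data$leaf)),
                       .groups = "drop")
  }) |>
    dplyr::bind_rows()
}

# Resolve metabolite regulation labels from a differential result.
# `diff_results` may carry an `entry_id` column (preferred) or be matched
# by feature_id against entry ids.
regulation_of <- function(entry_ids, diff_results) {
  if (is.null(diff_results)) return(rep("none", length(entry_ids)))
  dr <- tibble::as_tibble(diff_results)
  key <- if ("entry_id" %in% names(dr)) dr$entry_id else dr$feature_id
  reg <- ifelse(dr$significant, dr$direction, "none")
  out <- reg[match(entry_ids, key)]
  ifelse(is.na(out), "none", out)
}

# Map correlation-table metabolite labels onto reaction participant
# entry ids (exact entry id, else normalized entry name).
match_corr_metabolites <- function(correlations, parts) {
  m <- correlations$metabolite
  by_id <- parts$entry_id[match(m, parts$entry_id)]
  by_name <- parts$entry_id[match(normalize_name(m),
                                  normalize_name(parts$label))]
  dplyr::coalesce(by_id, by_name)
}

#' Build the Bio-Sankey network for a metabolic reaction
#'
#' The biological view: the background is every organism the knowledge
#' base lists as able to perform the reaction. Substrate and product
#' metabolite nodes connect to the enzyme(s) of the reaction; each enzyme
#' connects into the taxonomy of the organisms using it, and the taxonomy
#' fans out phylum -> class -> order -> family -> genus -> species. Band
#' widths are the number of distinct species beneath each branch.
#' Metabolite nodes carry up/down regulation from the differential
#' analysis. When a correlation table is supplied, the link into any taxon
#' significantly correlated (p <= `alpha`) with the substrate or product
#' is colored by the correlation sign and emphasized.
#'
#' @param reaction_id reaction in the knowledge base.
#' @param kb a [metab_kb()].
#' @param diff_results optional [differential_analysis()] result carrying
#'   `entry_id`s (see [run_dmoa()]) for node regulation.
#' @param correlations optional [correlate()] result for the overlay.
#' @param alpha emphasis threshold for the correlation overlay.
#' @return a `sankey_graph` (variant `"bio"`).
#' @export
build_bio_sankey <- function(reaction_id, kb, diff_results = NULL,
                             correlations = NULL, alpha = 0.05) {
  stopifnot(inherits(kb, "metab_kb"))
  ctx <- reaction_context(kb, reaction_id)
  parts <- ctx$parts
  enzymes <- if (length(ctx$enzymes) > 0) ctx$enzymes else "unknown enzyme"
  orgs <- ctx$orgs
  has_orgs <- nrow(orgs) > 0

  met_nodes <- tibble::tibble(
    node_id = node_id_of("metabolite", parts$label),
    kind = "metabolite", label = parts$label,
    regulation = regulation_of(parts$entry_id, diff_results),
    column = SANKEY_COLUMNS[["metabolite"]])
  enz_nodes <- tibble::tibble(
    node_id = node_id_of("enzyme", enzymes), kind = "enzyme",
    label = enzymes, regulation = "none",
    column = SANKEY_COLUMNS[["enzyme"]])
  nodes <- dplyr::distinct(dplyr::bind_rows(met_nodes, enz_nodes))

  links <- NULL
  if (has_orgs) {
    orgs$ec <- ifelse(is.na(orgs$ec_number) | orgs$ec_number == "",
                      enzymes[1], orgs$ec_number)
    # metabolite -> enzyme: width = distinct species using that enzyme
    enz_width <- orgs |>
      dplyr::group_by(ec = .data$ec) |>
      dplyr::summarise(width = dplyr::n_distinct(.data$org_code),
                       .groups = "drop")
    me <- tidyr::expand_grid(label = parts$label, ec = enz_width$ec) |>
      dplyr::distinct() |>
      dplyr::left_join(enz_width, by = "ec") |>
      dplyr::transmute(source = node_id_of("metabolite", .data$label),
                       target = node_id_of("enzyme", .data$ec),
                       width = .data$width)
    # enzyme -> phylum: distinct species per (enzyme, phylum)
    ep <- orgs |>
      dplyr::group_by(ec = .data$ec, phylum = .data$phylum) |>
      dplyr::summarise(width = dplyr::n_distinct(.data$org_code),
                       .groups = "drop") |>
      dplyr::transmute(source = node_id_of("enzyme", .data$ec),
                       target = node_id_of("phylum", .data$phylum),
                       width = .data$width)
    tax <- lineage_links(orgs[, TAXONOMY_RANKS], leaf = orgs$org_code)
    tl <- tax |>
      dplyr::transmute(source = node_id_of(.data$src_kind, .data$src_label),
                       target = node_id_of(.data$dst_kind, .data$dst_label),
                       width = .data$width)
    links <- dplyr::bind_rows(me, ep, tl)
    tax_nodes <- purrr::map(TAXONOMY_RANKS, \(rk) tibble::tibble(
      node_id = node_id_of(rk, unique(orgs[[rk]])), kind = rk,
      label = unique(orgs[[rk]]), regulation = "none",
      column = SANKEY_COLUMNS[[rk]]))
    nodes <- dplyr::distinct(dplyr::bind_rows(nodes, tax_nodes))
  } else {
    links <- tidyr::expand_grid(label = unique(parts$label),
                                ec = enzymes) |>
      dplyr::transmute(source = node_id_of("metabolite", .data$label),
                       target = node_id_of("enzyme", .data$ec),
                       width = 1L)
  }
  links$color_class <- "background"
  links$emphasized <- FALSE

  if (!is.null(correlations) && has_orgs && nrow(correlations) > 0) {
    cr <- tibble::as_tibble(correlations)
    cr$entry_id <- match_corr_metabolites(cr, parts)
    cr <- cr[!is.na(cr$entry_id) & cr$p_value <= alpha & !cr$degenerate, ]
    if (nrow(cr) > 0) {
      cr$taxon_label <- purrr::map2_chr(cr$taxon, cr$rank, \(t, rk)
        parse_lineage(t)[[rk]])
      # strongest correlation decides the color when substrate and
      # product both correlate with the same taxon
      cr <- cr |>
        dplyr::group_by(.data$rank, .data$taxon_label) |>
        dplyr::slice_max(abs(.data$coefficient), n = 1,
                         with_ties = FALSE) |>
        dplyr::ungroup()
      hit_ids <- node_id_of(cr$rank, cr$taxon_label)
      hit <- match(links$target, hit_ids)
      sel <- !is.na(hit)
      links$color_class[sel] <- ifelse(cr$coefficient[hit[sel]] >= 0,
                                       "positive", "negative")
      links$emphasized[sel] <- TRUE
    }
  }
  new_sankey_graph(reaction_id, "bio", nodes, links)
}

#' Build the STA-Sankey network for a metabolic reaction
#'
#' The statistical view, dual to [build_bio_sankey()]: the background is
#' every taxon significantly correlated (p <= `alpha`) with the reaction's
#' substrate or product, its chain colored by the correlation sign; a
#' taxon is emphasized when it ALSO appears in the knowledge base's
#' organism list for the reaction, i.e. when the statistical association
#' has biological support. Taxonomy chains run from phylum down to the
#' rank of the correlation table; widths count the distinct finest-rank
#' taxa beneath each branch.
#'
#' @param reaction_id reaction in the knowledge base.
#' @param correlations a [correlate()] result covering the reaction's
#'   substrate/product metabolites.
#' @param kb a [metab_kb()].
#' @param alpha inclusion threshold for the statistical background.
#' @return a `sankey_graph` (variant `"sta"`).
#' @export
build_sta_sankey <- function(reaction_id, correlations, kb, alpha = 0.05) {
  stopifnot(inherits(kb, "metab_kb"))
  ctx <- reaction_context(kb, reaction_id)
  parts <- ctx$parts
  enzymes <- if (length(ctx$enzymes) > 0) ctx$enzymes else "unknown enzyme"

  cr <- tibble::as_tibble(correlations)
  cr$entry_id <- match_corr_metabolites(cr, parts)
  cr <- cr[!is.na(cr$entry_id) & cr$p_value <= alpha & !cr$degenerate, ]
  cr <- cr |>
    dplyr::group_by(.data$taxon) |>
    dplyr::slice_max(abs(.data$coefficient), n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  met_nodes <- tibble::tibble(
    node_id = node_id_of("metabolite", parts$label),
    kind = "metabolite", label = parts$label, regulation = "none",
    column = SANKEY_COLUMNS[["metabolite"]])
  enz_nodes <- tibble::tibble(
    node_id = node_id_of("enzyme", enzymes), kind = "enzyme",
    label = enzymes, regulation = "none",
    column = SANKEY_COLUMNS[["enzyme"]])
  nodes <- dplyr::distinct(dplyr::bind_rows(met_nodes, enz_nodes))

  if (nrow(cr) == 0) {
    warning("no taxon is significantly correlated with reaction ",
            reaction_id, call. = FALSE)
    links <- tidyr::expand_grid(label = unique(parts$label), ec = enzymes) |>
      dplyr::transmute(source = node_id_of("metabolite", .data$label),
                       target = node_id_of("enzyme", .data$ec),
                       width = 1L, color_class = "background",
                       emphasized = FALSE)
    return(new_sankey_graph(reaction_id, "sta", nodes, links))
  }

  finest <- cr$rank[1]
  lin <- parse_lineage(cr$taxon)
  n_leaves <- nrow(cr)
  sign_of <- function(leaves) {
    co <- cr$coefficient[match(leaves, cr$taxon)]
    if (max(co) >= abs(min(co))) "positive" else "negative"
  }
  me <- tidyr::expand_grid(label = unique(parts$label), ec = enzymes) |>
    dplyr::transmute(source = node_id_of("metabolite", .data$label),
                     target = node_id_of("enzyme", .data$ec),
                     width = n_leaves, color_class = "background",
                     emphasized = FALSE)
  ep <- tibble::tibble(phylum = lin$phylum, leaf = cr$taxon) |>
    dplyr::group_by(.data$phylum) |>
    dplyr::summarise(width = dplyr::n_distinct(.data$leaf),
                     color_class = sign_of(unique(.data$leaf)),
                     .groups = "drop") |>
    tidyr::expand_grid(ec = enzymes) |>
    dplyr::transmute(source = node_id_of("enzyme", .data$ec),
                     target = node_id_of("phylum", .data$phylum),
                     width = .data$width, color_class = .data$color_class,
                     emphasized = FALSE)
  tl <- NULL
  if (match(finest, TAXONOMY_RANKS) > 1) {
    tl <- lineage_links(lin, leaf = cr$taxon, finest = finest) |>
      dplyr::mutate(color_class = purrr::map_chr(.data$leaves, sign_of)) |>
      dplyr::transmute(source = node_id_of(.data$src_kind, .data$src_label),
                       target = node_id_of(.data$dst_kind, .data$dst_label),
                       width = .data$width, color_class = .data$color_class,
                       emphasized = FALSE)
  }
  links <- dplyr::bind_rows(me, ep, tl)

  ranks_used <- TAXONOMY_RANKS[seq_len(match(finest, TAXONOMY_RANKS))]
  tax_nodes <- purrr::map(ranks_used, \(rk) tibble::tibble(
    node_id = node_id_of(rk, unique(lin[[rk]])), kind = rk,
    label = unique(lin[[rk]]), regulation = "none",
    column = SANKEY_COLUMNS[[rk]]))
  nodes <- dplyr::distinct(dplyr::bind_rows(nodes, tax_nodes))

  # biological support: the correlated taxon also appears among the
  # knowledge base's organisms for this reaction, matched at the finest
  # rank by normalized name
  if (nrow(ctx$orgs) > 0) {
    kb_labels <- normalize_name(ctx$orgs[[finest]])
    supported <- normalize_name(lin[[finest]]) %in% kb_labels
    leaf_nodes <- node_id_of(finest, lin[[finest]][supported])
    links$emphasized[links$target %in% leaf_nodes &
                       links$color_class != "background"] <- TRUE
  }
  new_sankey_graph(reaction_id, "sta", nodes, links)
}
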