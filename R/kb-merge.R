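#' Merge metabolite source records into deduplicated entries
#'
#' Each contributing database exports one row per compound; the same
#' compound typically appears in several databases under different native
#' identifiers and synonym spellings. Two records are considered the same
#' compound when they share a KEGG ID, share an HMDB ID, or have an
#' identical normalized formula together with at least one identical
#' normalized name or synonym. Identity is closed transitively (connected
#' components of the evidence graph), so a record linked to a second by a
#' KEGG ID and to a third by an HMDB ID collapses all three into one entry.
#' Cross-references, synonyms, origin tags and source databases are
#' unioned; the canonical formula prefers a KEGG-sourced record, and every
#' distinct formula is retained in the `formulas` column.
#'
#' @param records tibble of source records with columns `source_db`,
#'   `native_id`, `kegg_id`, `hmdb_id`, `formula`, `name`, `synonyms`
#'   (`;`-joined), `origin_tags` (`;`-joined subset of the seven-tag
#'   vocabulary: mammal, archaea, fungi, bacteria, food_plant, drug,
#'   toxin_pollutant). Empty string or `NA` marks an absent field.
#' @return tibble of entries with columns `entry_id`, `name`, `formula`,
#'   `formulas`, `kegg_ids`, `hmdb_ids`, `names`, `origin_tags`,
#'   `source_dbs` (set columns `;`-joined, sorted). Records with no usable
#'   identifier (no KEGG ID, no HMDB ID and no name) are skipped with a
#'   per-record diagnostic, attached as the `"rejected"` attribute, and a
#'   single warning summarizes how many were dropped.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   source_db = c("kegg", "hmdb"), native_id = c("C00079", "HMDB0000159"),
#'   kegg_id = c("C00079", "C00079"), hmdb_id = c("", "HMDB0000159"),
#'   formula = "C9H11NO2", name = c("L-Phenylalanine", "Phenylalanine"),
#'   synonyms = c("Phe", ""), origin_tags = c("bacteria", "mammal"))
#' merge_sources(recs)
merge_sources <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("source_db", "native_id", "kegg_id", "hmdb_id",
              "formula", "name", "synonyms", "origin_tags")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0)
    stop_input("records lack column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(records) == 0) stop_input("records must be non-empty")
  records <- dplyr::mutate(records, dplyr::across(dplyr::all_of(needed),
                                                  \(x) {
                                                    x <- as.character(x)
                                                    x[is.na(x)] <- ""
                                                    x
                                                  }))
  bad_tags <- setdiff(unlist(split_set(records$origin_tags)), ORIGIN_TAGS)
  if (length(bad_tags) > 0)
    stop_input("unknown origin tag(s): ", paste(bad_tags, collapse = ", "))

  usable <- records$kegg_id != "" | records$hmdb_id != "" | records$name != ""
  rejected <- records[!usable, , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected$reason <- "no usable identifier (kegg_id, hmdb_id and name all empty)"
    warning(nrow(rejected), " record(s) rejected: no usable identifier",
            call. = FALSE)
  }
  records <- records[usable, , drop = FALSE]
  if (nrow(records) == 0) stop_input("no record has a usable identifier")

  n <- nrow(records)
  rec_names <- purrr::map2(records$name, records$synonyms, \(nm, syn) {
    unique(normalize_name(c(nm, strsplit(syn, ";", fixed = TRUE)[[1]])))
  }) |> purrr::map(\(v) v[v != ""])

  # Evidence edges: shared KEGG id, shared HMDB id, or
  # (same normalized formula AND a shared normalized name).
  key_edges <- function(keys) {
    grp <- split(seq_len(n), keys)[setdiff(unique(keys), "")]
    purrr::map(grp, \(ix) if (length(ix) > 1) cbind(ix[-length(ix)], ix[-1]))
  }
  form_keys <- purrr::map2(normalize_name(records$formula), rec_names,
                           \(f, nms) if (f == "" || length(nms) == 0)
                             character(0) else paste(f, nms))
  fk <- tibble::tibble(i = rep(seq_len(n), lengths(form_keys)),
                       key = unlist(form_keys))
  fgrp <- split(fk$i, fk$key)
  edges <- c(key_edges(records$kegg_id), key_edges(records$hmdb_id),
             purrr::map(fgrp, \(ix) {
               ix <- unique(ix)
               if (length(ix) > 1) cbind(ix[-length(ix)], ix[-1])
             }))
  em <- do.call(rbind, c(list(matrix(numeric(0), ncol = 2)),
                         purrr::compact(edges)))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(em) > 0) g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)$membership
  # Stable entry ids: components numbered by first record occurrence.
  first_ix <- tapply(seq_len(n), comp, min)
  ord <- rank(first_ix)
  comp_id <- sprintf("MB%05d", ord[as.character(comp)])

  entries <- tibble::tibble(rec = seq_len(n), entry_id = comp_id) |>
    dplyr::group_by(.data$entry_id) |>
    dplyr::summarise(
      name = {
        nm <- records$name[.data$rec]
        c(nm[nm != ""], "")[1]
      },
      formula = {
        f <- records$formula[.data$rec]
        src <- records$source_db[.data$rec]
        f_kegg <- f[src == "kegg" & f != ""]
        if (length(f_kegg) > 0) f_kegg[1] else c(f[f != ""], "")[1]
      },
      formulas = join_set(list(records$formula[.data$rec])),
      kegg_ids = join_set(list(records$kegg_id[.data$rec])),
      hmdb_ids = join_set(list(records$hmdb_id[.data$rec])),
      names = join_set(list(c(records$name[.data$rec],
                              unlist(strsplit(records$synonyms[.data$rec],
                                              ";", fixed = TRUE))))),
      origin_tags = join_set(list(unlist(strsplit(
        records$origin_tags[.data$rec], ";", fixed = TRUE)))),
      source_dbs = join_set(list(records$source_db[.data$rec])),
      .groups = "drop") |>
    dplyr::arrange(.data$entry_id)
  attr(entries, "rejected") <- tibble::as_tibble(rejected)
  entries
}

#' Re-export deduplicated entries as source records
#'
#' Inverse-direction helper used to check that deduplication is
#' idempotent: feeding the output back through [merge_sources()] must not
#' change the entry count. Identifier evidence (cross-references and the
#' canonical name) is exported; the formula field is left empty because
#' the per-record pairing of formula and name — which is what
#' formula-based merging keys on — no longer exists after entries have
#' been unioned.
#'
#' @param entries output of [merge_sources()].
#' @return a record tibble in the [merge_sources()] input shape.
#' @export
entries_as_records <- function(entries) {
  tibble::tibble(
    source_db = "merged",
    native_id = entries$entry_id,
    kegg_id = purrr::map_chr(split_set(entries$kegg_ids), \(v) c(v, "")[1]),
    hmdb_id = purrr::map_chr(split_set(entries$hmdb_ids), \(v) c(v, "")[1]),
    formula = "",
    name = entries$name,
    synonyms = entries$names,
    origin_tags = entries$origin_tags)
}

#' Assemble a knowledge base from merged entries and context tables
#'
#' Expands the compact set-valued entry table produced by
#' [merge_sources()] into the long-form component tables of a
#' [metab_kb()].
#'
#' @param entries output of [merge_sources()].
#' @param organisms,pathways,pathway_members,pathway_organisms,reactions,reaction_pathways,reaction_participants,reaction_enzymes,reaction_organisms
#'   see [metab_kb()]; defaults are empty tables.
#' @param manifest named list of bundle metadata.
#' @return a `metab_kb`.
#' @export
kb_from_entries <- function(entries,
                            organisms = empty_organisms(),
                            pathways = tibble::tibble(pathway_id = character(),
                                                      name = character()),
                            pathway_members = tibble::tibble(
                              pathway_id = character(), entry_id = character()),
                            pathway_organisms = tibble::tibble(
                              pathway_id = character(), org_code = character()),
                            reactions = tibble::tibble(reaction_id = character()),
                            reaction_pathways = tibble::tibble(
                              reaction_id = character(), pathway_id = character()),
                            reaction_participants = tibble::tibble(
                              reaction_id = character(), entry_id = character(),
                              role = character()),
                            reaction_enzymes = tibble::tibble(
                              reaction_id = character(), ec_number = character()),
                            reaction_organisms = tibble::tibble(
                              reaction_id = character(), org_code = character(),
                              ec_number = character()),
                            manifest = list()) {
  unnest_set <- function(col, out) {
    sets <- split_set(entries[[col]])
    tibble::tibble(entry_id = rep(entries$entry_id, lengths(sets)),
                   value = unlist(sets)) |>
      rlang::set_names(c("entry_id", out))
  }
  xrefs <- dplyr::bind_rows(
    dplyr::mutate(unnest_set("kegg_ids", "xref_id"), db = "kegg"),
    dplyr::mutate(unnest_set("hmdb_ids", "xref_id"), db = "hmdb")) |>
    dplyr::select("entry_id", "db", "xref_id")
  metab_kb(
    entries = entries[, c("entry_id", "name", "formula", "formulas")],
    entry_xrefs = xrefs,
    entry_names = unnest_set("names", "name"),
    entry_origins = unnest_set("origin_tags", "origin_tag"),
    entry_sources = unnest_set("source_dbs", "source_db"),
    organisms = organisms, pathways = pathways,
    pathway_members = pathway_members, pathway_organisms = pathway_organisms,
    reactions = reactions, reaction_pathways = reaction_pathways,
    reaction_participants = reaction_participants,
    reaction_enzymes = reaction_enzymes,
    reaction_organisms = reaction_organisms, manifest = manifest)
}

empty_organisms <- function() {
  tibble::tibble(org_code = character(), name = character(),
                 kind = character(), phylum = character(),
                 class = character(), order = character(),
                 family = character(), genus = character(),
                 species = character())
}
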