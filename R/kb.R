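#' Construct a metabolite-origin knowledge base
#'
#' A `metab_kb` bundles everything the pipeline needs offline: deduplicated
#' metabolite entries with cross-references and per-source origin evidence,
#' organisms with full taxonomic lineages, pathways with their member
#' metabolites and carrying organisms, and reactions with substrates,
#' products, enzymes and the organisms able to perform them. All component
#' tables are plain tibbles of character columns, normalized long-form
#' (one row per membership fact), which keeps the on-disk bundle diff-able
#' and the round trip lossless.
#'
#' @param entries tibble with columns `entry_id`, `name`, `formula`,
#'   `formulas` (all known formulas, `;`-joined).
#' @param entry_xrefs tibble `entry_id`, `db` ("kegg"/"hmdb"), `xref_id`.
#' @param entry_names tibble `entry_id`, `name` (all names incl. synonyms).
#' @param entry_origins tibble `entry_id`, `origin_tag` (seven-tag vocabulary).
#' @param entry_sources tibble `entry_id`, `source_db`.
#' @param organisms tibble `org_code`, `name`, `kind` (animal/bacteria/
#'   archaea/fungi/other) plus the six rank columns phylum..species.
#' @param pathways tibble `pathway_id`, `name`.
#' @param pathway_members tibble `pathway_id`, `entry_id`.
#' @param pathway_organisms tibble `pathway_id`, `org_code`.
#' @param reactions tibble `reaction_id`.
#' @param reaction_pathways tibble `reaction_id`, `pathway_id`.
#' @param reaction_participants tibble `reaction_id`, `entry_id`,
#'   `role` ("substrate"/"product").
#' @param reaction_enzymes tibble `reaction_id`, `ec_number`.
#' @param reaction_organisms tibble `reaction_id`, `org_code`, `ec_number`.
#' @param manifest named list of bundle metadata (a `format_version` is
#'   added if absent).
#'
#' @return an object of class `metab_kb`.
#' @seealso [merge_sources()] to build entries from raw source records,
#'   [write_kb()]/[read_kb()] for the on-disk bundle, [generate_kb()] and
#'   [phenylalanine_kb()] for synthetic instances.
#' @export
metab_kb <- function(entries, entry_xrefs, entry_names, entry_origins,
                     entry_sources, organisms, pathways, pathway_members,
                     pathway_organisms, reactions, reaction_pathways,
                     reaction_participants, reaction_enzymes,
                     reaction_organisms, manifest = list()) {
  manifest$format_version <- manifest$format_version %||% "1"
  kb <- structure(
    list(entries = as_chr_tbl(entries),
         entry_xrefs = as_chr_tbl(entry_xrefs),
         entry_names = as_chr_tbl(entry_names),
         entry_origins = as_chr_tbl(entry_origins),
         entry_sources = as_chr_tbl(entry_sources),
         organisms = as_chr_tbl(organisms),
         pathways = as_chr_tbl(pathways),
         pathway_members = as_chr_tbl(pathway_members),
         pathway_organisms = as_chr_tbl(pathway_organisms),
         reactions = as_chr_tbl(reactions),
         reaction_pathways = as_chr_tbl(reaction_pathways),
         reaction_participants = as_chr_tbl(reaction_participants),
         reaction_enzymes = as_chr_tbl(reaction_enzymes),
         reaction_organisms = as_chr_tbl(reaction_organisms),
         manifest = manifest),
    class = "metab_kb")
  validate_kb(kb)
  kb
}

as_chr_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  dplyr::mutate(x, dplyr::across(dplyr::everything(), \(v) {
    v <- as.character(v)
    v[is.na(v)] <- ""
    v
  }))
}

KB_TABLES <- c("entries", "entry_xrefs", "entry_names", "entry_origins",
               "entry_sources", "organisms", "pathways", "pathway_members",
               "pathway_organisms", "reactions", "reaction_pathways",
               "reaction_participants", "reaction_enzymes",
               "reaction_organisms")

#' Validate knowledge-base referential integrity
#'
#' Checks the structural invariants: unique entry/organism/pathway/reaction
#' identifiers, no KEGG or HMDB ID shared by two entries, origin tags drawn
#' from the seven-tag vocabulary, non-empty pathway membership, every
#' membership/participant/organism row resolving to a contained object, and
#' complete six-rank lineages for microbial organisms (missing interior
#' ranks must use the explicit `"unclassified"` placeholder, never `NA`).
#'
#' @param kb a `metab_kb`.
#' @return `kb`, invisibly; errors describe the first violated invariant.
#' @export
validate_kb <- function(kb) {
  stopifnot(inherits(kb, "metab_kb"))
  ent <- kb$entries
  if (anyDuplicated(ent$entry_id))
    stop_input("duplicate entry_id in entries")
  dup <- kb$entry_xrefs |>
    dplyr::distinct(.data$db, .data$xref_id, .data$entry_id) |>
    dplyr::count(.data$db, .data$xref_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0)
    stop_input("cross-reference ", dup$db[1], ":", dup$xref_id[1],
               " maps to more than one entry")
  bad_tag <- setdiff(unique(kb$entry_origins$origin_tag), ORIGIN_TAGS)
  if (length(bad_tag) > 0)
    stop_input("unknown origin tag(s): ", paste(bad_tag, collapse = ", "))
  if (anyDuplicated(kb$organisms$org_code))
    stop_input("duplicate org_code in organisms")
  if (anyDuplicated(kb$pathways$pathway_id))
    stop_input("duplicate pathway_id in pathways")
  empty_pw <- setdiff(kb$pathways$pathway_id, kb$pathway_members$pathway_id)
  if (length(empty_pw) > 0)
    stop_input("pathway without member metabolites: ",
               paste(empty_pw, collapse = ", "))
  check_fk <- function(child, col, parent, what) {
    bad <- setdiff(child[[col]], parent)
    if (length(bad) > 0)
      stop_input(what, " references unknown id(s): ",
                 paste(utils::head(bad, 3), collapse = ", "))
  }
  check_fk(kb$entry_xrefs, "entry_id", ent$entry_id, "entry_xrefs")
  check_fk(kb$entry_names, "entry_id", ent$entry_id, "entry_names")
  check_fk(kb$entry_origins, "entry_id", ent$entry_id, "entry_origins")
  check_fk(kb$pathway_members, "entry_id", ent$entry_id, "pathway_members")
  check_fk(kb$pathway_members, "pathway_id", kb$pathways$pathway_id,
           "pathway_members")
  check_fk(kb$pathway_organisms, "pathway_id", kb$pathways$pathway_id,
           "pathway_organisms")
  check_fk(kb$pathway_organisms, "org_code", kb$organisms$org_code,
           "pathway_organisms")
  check_fk(kb$reaction_pathways, "reaction_id", kb$reactions$reaction_id,
           "reaction_pathways")
  check_fk(kb$reaction_pathways, "pathway_id", kb$pathways$pathway_id,
           "reaction_pathways")
  check_fk(kb$reaction_participants, "reaction_id", kb$reactions$reaction_id,
           "reaction_participants")
  check_fk(kb$reaction_participants, "entry_id", ent$entry_id,
           "reaction_participants")
  check_fk(kb$reaction_organisms, "reaction_id", kb$reactions$reaction_id,
           "reaction_organisms")
  check_fk(kb$reaction_organisms, "org_code", kb$organisms$org_code,
           "reaction_organisms")
  no_part <- setdiff(kb$reactions$reaction_id,
                     kb$reaction_participants$reaction_id)
  if (length(no_part) > 0)
    stop_input("reaction without substrates or products: ",
               paste(no_part, collapse = ", "))
  microbes <- dplyr::filter(kb$organisms, .data$kind %in% MICROBIAL_TAGS)
  if (nrow(microbes) > 0) {
    ranks <- microbes[, TAXONOMY_RANKS, drop = FALSE]
    incomplete <- apply(is.na(ranks) | ranks == "", 1, any)
    if (any(incomplete))
      stop_input("microbial organism without a complete six-rank lineage: ",
                 microbes$org_code[which(incomplete)[1]],
                 " (use the '", MISSING_RANK, "' placeholder)")
  }
  invisible(kb)
}

#' @export
print.metab_kb <- function(x, ...) {
  cat("<metab_kb>", nrow(x$entries), "entries,",
      nrow(x$organisms), "organisms,",
      nrow(x$pathways), "pathways,",
      nrow(x$reactions), "reactions\n")
  invisible(x)
}

#' Summarize a knowledge base
#'
#' @param x a `metab_kb`.
#' @param ... unused.
#' @return one-row tibble with object counts and the number of entries
#'   carrying origin evidence.
#' @method glance metab_kb
#' @export
glance.metab_kb <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_with_origin = dplyr::n_distinct(x$entry_origins$entry_id),
    n_organisms = nrow(x$organisms),
    n_bacteria = sum(x$organisms$kind == "bacteria"),
    n_pathways = nrow(x$pathways),
    n_reactions = nrow(x$reactions))
}
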