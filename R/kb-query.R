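#' Match query metabolites against a knowledge base
#'
#' Queries are matched with the precedence KEGG ID > HMDB ID > exact
#' normalized name or synonym, so an identifier always beats a name and a
#' query resolves to at most one entry. When the KEGG and HMDB IDs of one
#' query resolve to different entries, the KEGG match wins and the row is
#' annotated `id_conflict`; a single warning reports how many conflicts
#' occurred.
#'
#' @param queries tibble with columns `name`, `kegg_id`, `hmdb_id` (any may
#'   be empty/`NA`, but each row needs at least one non-empty field).
#' @param kb a [metab_kb()].
#' @return tibble: the query columns plus `entry_id` (`NA` when unmatched),
#'   `matched_by` (`"kegg"`, `"hmdb"`, `"name"` or `NA`) and `note`
#'   (`"id_conflict"` where KEGG and HMDB disagreed).
#' @export
match_metabolites <- function(queries, kb) {
  stopifnot(inherits(kb, "metab_kb"))
  queries <- tibble::as_tibble(queries)
  for (col in c("name", "kegg_id", "hmdb_id"))
    if (!col %in% names(queries)) queries[[col]] <- ""
  queries <- dplyr::mutate(
    queries,
    dplyr::across(c("name", "kegg_id", "hmdb_id"), \(x) {
      x <- as.character(x)
      x[is.na(x)] <- ""
      x
    }))
  if (any(queries$name == "" & queries$kegg_id == "" & queries$hmdb_id == ""))
    stop_input("every query needs at least one of name, kegg_id, hmdb_id")

  xr <- kb$entry_xrefs
  kegg_index <- stats::setNames(xr$entry_id[xr$db == "kegg"],
                                xr$xref_id[xr$db == "kegg"])
  hmdb_index <- stats::setNames(xr$entry_id[xr$db == "hmdb"],
                                xr$xref_id[xr$db == "hmdb"])
  nm <- kb$entry_names |>
    dplyr::mutate(key = normalize_name(.data$name)) |>
    dplyr::filter(.data$key != "") |>
    dplyr::distinct(.data$key, .keep_all = TRUE)   # first entry wins ties
  name_index <- stats::setNames(nm$entry_id, nm$key)

  by_kegg <- unname(kegg_index[queries$kegg_id])
  by_hmdb <- unname(hmdb_index[queries$hmdb_id])
  by_name <- unname(name_index[normalize_name(queries$name)])

  entry_id <- dplyr::coalesce(by_kegg, by_hmdb, by_name)
  matched_by <- dplyr::case_when(
    !is.na(by_kegg) ~ "kegg",
    !is.na(by_hmdb) ~ "hmdb",
    !is.na(by_name) ~ "name",
    TRUE ~ NA_character_)
  conflict <- !is.na(by_kegg) & !is.na(by_hmdb) & by_kegg != by_hmdb
  if (any(conflict))
    warning(sum(conflict), " query/queries with conflicting KEGG/HMDB IDs; ",
            "matched by KEGG ID", call. = FALSE)
  out <- dplyr::mutate(queries,
                       entry_id = entry_id,
                       matched_by = matched_by,
                       note = ifelse(conflict, "id_conflict", NA_character_))
  class(out) <- c("metab_matches", class(out))
  out
}

#' Origin category from a set of evidence tags
#'
#' Decision rule over the seven-tag evidence vocabulary, applied to each
#' element of a list of tag sets:
#' mammal together with any microbial tag (archaea, fungi or bacteria)
#' means Co-Metabolism; mammal alone among the biological tags means Host;
#' microbial tags without mammal mean Microbiota; otherwise the first
#' present of food_plant > drug > toxin_pollutant decides Food, Drug or
#' Environment; an empty set is Unknown.
#'
#' @param evidence list of character vectors of origin tags (a single
#'   character vector is treated as one set).
#' @return factor with levels Host, Microbiota, Co-Metabolism, Food, Drug,
#'   Environment, Unknown.
#' @export
#' @examples
#' origin_category(list(c("mammal", "bacteria"), "mammal", character(0)))
origin_category <- function(evidence) {
  if (!is.list(evidence)) evidence <- list(evidence)
  bad <- setdiff(unlist(evidence), ORIGIN_TAGS)
  if (length(bad) > 0)
    stop_input("unknown origin tag(s): ", paste(bad, collapse = ", "))
  cat <- vapply(evidence, function(tags) {
    host <- "mammal" %in% tags
    microbe <- any(MICROBIAL_TAGS %in% tags)
    if (host && microbe) return("Co-Metabolism")
    if (host) return("Host")
    if (microbe) return("Microbiota")
    if ("food_plant" %in% tags) return("Food")
    if ("drug" %in% tags) return("Drug")
    if ("toxin_pollutant" %in% tags) return("Environment")
    "Unknown"
  }, character(1))
  factor(cat, levels = ORIGIN_CATEGORIES)
}

#' Classify matched metabolites by origin
#'
#' Joins the matches against the knowledge base's origin evidence and
#' assigns each query exactly one of the six origin categories, or Unknown
#' when the query is unmatched or its entry carries no origin evidence.
#'
#' @param matches output of [match_metabolites()].
#' @param kb the same `metab_kb` the matches were produced against.
#' @return tibble of class `origin_calls`: `query_name`, `entry_id`,
#'   `category` (factor over the seven categories), `evidence`
#'   (`;`-joined supporting tags).
#' @export
classify_origins <- function(matches, kb) {
  stopifnot(inherits(kb, "metab_kb"))
  matches <- tibble::as_tibble(matches)
  ev <- kb$entry_origins |>
    dplyr::group_by(.data$entry_id) |>
    dplyr::summarise(evidence = join_set(list(.data$origin_tag)),
                     .groups = "drop")
  out <- matches |>
    dplyr::left_join(ev, by = "entry_id") |>
    dplyr::mutate(
      evidence = ifelse(is.na(.data$entry_id) | is.na(.data$evidence),
                        "", .data$evidence),
      category = origin_category(split_set(.data$evidence))) |>
    dplyr::select(query_name = "name", "entry_id", "category", "evidence")
  class(out) <- c("origin_calls", class(out))
  out
}

#' Tally origin calls by category
#'
#' @param calls output of [classify_origins()].
#' @param collapse_others collapse Food, Drug and Environment into a single
#'   "Others" category, the grouping used for compact bar plots.
#' @return tibble `category`, `n`; categories with zero calls are kept, and
#'   counts always sum to `nrow(calls)`.
#' @export
category_counts <- function(calls, collapse_others = FALSE) {
  if (nrow(calls) == 0) stop_input("calls must be non-empty")
  cat <- factor(as.character(calls$category), levels = ORIGIN_CATEGORIES)
  if (collapse_others) {
    lv <- c("Host", "Microbiota", "Co-Metabolism", "Others", "Unknown")
    cat <- factor(ifelse(as.character(cat) %in%
                           c("Food", "Drug", "Environment"),
                         "Others", as.character(cat)), levels = lv)
  }
  tibble::tibble(category = levels(cat),
                 n = as.integer(table(cat)[levels(cat)]))
}
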