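#' Write a knowledge base to a TSV bundle
#'
#' The on-disk format is a directory of plain TSV tables (one per
#' component table of the [metab_kb()]) plus a `manifest.json` carrying the
#' format version and any bundle metadata. Everything is written as
#' character data in a fixed column and row order, so
#' write -> read -> write is byte-identical and bundles diff cleanly under
#' version control.
#'
#' @param kb a `metab_kb`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_kb <- function(kb, dir) {
  stopifnot(inherits(kb, "metab_kb"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in KB_TABLES)
    readr::write_tsv(kb[[tab]], file.path(dir, paste0(tab, ".tsv")),
                     na = "", progress = FALSE)
  manifest <- kb$manifest
  manifest <- manifest[order(names(manifest))]
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a knowledge base bundle
#'
#' Loads the TSV tables written by [write_kb()], re-validates referential
#' integrity, and returns the reconstructed `metab_kb`.
#'
#' @param dir bundle directory.
#' @return a `metab_kb`.
#' @export
read_kb <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path))
    stop_input("not a knowledge-base bundle (missing manifest.json): ", dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  tabs <- lapply(KB_TABLES, function(tab) {
    path <- file.path(dir, paste0(tab, ".tsv"))
    if (!file.exists(path)) stop_input("bundle is missing table: ", tab)
    readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_character()), na = character(),
      progress = FALSE)
  })
  names(tabs) <- KB_TABLES
  do.call(metab_kb, c(tabs, list(manifest = as.list(manifest))))
}
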