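# Orchestration of the two analysis modes.
#
# SMOA (simple mode) needs only a metabolite list with KEGG/HMDB ids:
# origin classification, origin-scoped pathway enrichment and biological
# Sankey networks. DMOA (deep mode) takes the full metabolite table,
# microbiome table and sample information, adding differential analysis,
# taxon-metabolite correlation, statistical Sankey networks, per-origin
# summary networks and the pathway-overlap report.

MPEA_SCOPES <- c("host", "microbiota", "cometabolism", "all_host",
                 "all_cometabolism")

scope_of_category <- c(Host = "host", Microbiota = "microbiota",
                       `Co-Metabolism` = "cometabolism")

write_report <- function(x, out_dir, name) {
  readr::write_tsv(tibble::as_tibble(x), file.path(out_dir, name),
                   na = "", progress = FALSE)
}

run_manifest <- function(out_dir, mode, config, kb) {
  manifest <- list(
    mode = mode,
    package_version = as.character(utils::packageVersion("metaborigin")),
    config = config,
    kb_manifest = kb$manifest,
    n_entries = nrow(kb$entries))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# Origin-split MPEA over the five scopes: the three origin scopes test
# their own differential subsets, the two pooled comparison modes test
# all differential metabolites against the host / cometabolism reference.
mpea_all_scopes <- function(diff_calls, kb, host_org, alpha) {
  diff_by_cat <- split(diff_calls$entry_id, as.character(diff_calls$category))
  all_ids <- diff_calls$entry_id
  purrr::map(stats::setNames(MPEA_SCOPES, MPEA_SCOPES), function(scope) {
    ids <- if (startsWith(scope, "all_")) all_ids
    else diff_by_cat[[names(scope_of_category)[
      scope_of_category == scope]]]
    if (is.null(ids) || length(ids) == 0 || all(is.na(ids))) return(NULL)
    lib <- tryCatch(
      build_reference_library(kb, scope, host_org = host_org),
      error = function(e) NULL)
    if (is.null(lib)) return(NULL)
    tryCatch(suppressWarnings(run_mpea(ids[!is.na(ids)], lib,
                                       alpha = alpha)),
             error = function(e) NULL)
  })
}

# Sankey graphs for every significant pathway's differential reactions.
sankey_for_significant <- function(mpea_list, diff_ids, kb, diff_results,
                                   correlations, alpha, out_dir,
                                   variants = "bio") {
  sig_pw <- unique(unlist(purrr::map(mpea_list, function(m)
    if (is.null(m)) NULL else m$pathway_id[m$significant])))
  graphs <- list()
  for (pw in sig_pw) {
    rxns <- reactions_for_pathway(pw, diff_ids, kb)
    for (rid in rxns$reaction_id) {
      if ("bio" %in% variants) {
        g <- build_bio_sankey(rid, kb, diff_results = diff_results,
                              correlations = correlations, alpha = alpha)
        export_network(g, file.path(out_dir,
                                    paste0("bio_sankey_", rid, ".json")),
                       "json")
        graphs[[paste0("bio_", rid)]] <- g
      }
      if ("sta" %in% variants && !is.null(correlations)) {
        g <- suppressWarnings(
          build_sta_sankey(rid, correlations, kb, alpha = alpha))
        export_network(g, file.path(out_dir,
                                    paste0("sta_sankey_", rid, ".json")),
                       "json")
        graphs[[paste0("sta_", rid)]] <- g
      }
    }
  }
  graphs
}

#' Run the simple analysis mode on a metabolite list
#'
#' Matches the query metabolites against the knowledge base, classifies
#' their origins, runs the origin-scoped pathway enrichment treating every
#' matched metabolite as "of interest", and writes biological Sankey
#' networks for each significant pathway. All tables land in `out_dir` as
#' TSV, networks as JSON, plus a JSON run manifest.
#'
#' @param metabolites tibble with columns `name`, `kegg_id`, `hmdb_id`
#'   (or a path to such a TSV/CSV).
#' @param kb a [metab_kb()] or a bundle directory path.
#' @param out_dir output directory.
#' @param host_org host organism code.
#' @param alpha enrichment significance level.
#' @return (invisibly) list with `origin_calls`, `category_counts`,
#'   `mpea` (per scope) and `sankey` graphs.
#' @export
run_smoa <- function(metabolites, kb, out_dir, host_org = "hsa",
                     alpha = 0.05) {
  if (is.character(kb)) kb <- read_kb(kb)
  if (is.character(metabolites))
    metabolites <- read_abundance(metabolites, n_id_cols = 3)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  matches <- match_metabolites(metabolites[, c("name", "kegg_id",
                                               "hmdb_id")], kb)
  calls <- classify_origins(matches, kb)
  if (all(is.na(calls$entry_id)))
    stop_input("no query metabolite matched the knowledge base")
  write_report(calls, out_dir, "origin_calls.tsv")
  counts <- category_counts(calls)
  write_report(counts, out_dir, "category_counts.tsv")
  matched <- calls[!is.na(calls$entry_id), ]
  mpea <- mpea_all_scopes(matched, kb, host_org, alpha)
  for (scope in names(mpea))
    if (!is.null(mpea[[scope]]))
      write_report(mpea[[scope]], out_dir, paste0("mpea_", scope, ".tsv"))
  graphs <- sankey_for_significant(
    mpea[c("host", "microbiota", "cometabolism")], matched$entry_id, kb,
    diff_results = NULL, correlations = NULL, alpha = alpha,
    out_dir = out_dir, variants = "bio")
  run_manifest(out_dir, "smoa",
               list(host_org = host_org, alpha = alpha,
                    n_queries = nrow(metabolites)), kb)
  invisible(list(origin_calls = calls, category_counts = counts,
                 mpea = mpea, sankey = graphs))
}

#' Run the deep analysis mode on a full study
#'
#' The complete pipeline: pretreatment (imputation + normalization) of the
#' metabolite table, origin classification, two-group differential
#' analysis of metabolites and taxa, origin-scoped pathway enrichment of
#' the differential metabolites, taxon-metabolite correlation at the
#' requested rank, biological and statistical Sankey networks for the
#' reactions of significant pathways, per-origin summary networks, and
#' the enriched-pathway overlap report. All tables are written as TSV,
#' networks as JSON (summary networks additionally as GraphML and HTML),
#' plus a JSON run manifest.
#'
#' @param metab_table metabolite tibble (`name`, `kegg_id`, `hmdb_id` +
#'   sample columns) or path.
#' @param taxa_table species-level taxa tibble (lineage + samples) or
#'   path.
#' @param sample_info tibble `sample_id`, `group` or path.
#' @param kb a [metab_kb()] or bundle directory.
#' @param out_dir output directory.
#' @param host_org host organism code.
#' @param impute_method,normalize_method pretreatment choices (see
#'   [impute_missing()], [normalize_abundance()]).
#' @param test differential test (see [differential_analysis()]).
#' @param alpha significance level for differential analysis, enrichment
#'   and correlation.
#' @param corr_method,corr_rank correlation choices (see [correlate()]).
#' @param summary_p p-value cutoff for summary-network edges.
#' @param seed seed for the stochastic pretreatment/correlation steps.
#' @return (invisibly) list with all intermediate results.
#' @export
run_dmoa <- function(metab_table, taxa_table, sample_info, kb, out_dir,
                     host_org = "hsa", impute_method = "min",
                     normalize_method = "log", test = "mannwhitney",
                     alpha = 0.05, corr_method = "spearman",
                     corr_rank = "genus", summary_p = 0.01, seed = 1L) {
  if (is.character(kb)) kb <- read_kb(kb)
  if (is.character(metab_table))
    metab_table <- read_abundance(metab_table, n_id_cols = 3)
  if (is.character(taxa_table))
    taxa_table <- read_abundance(taxa_table, n_id_cols = 1)
  if (is.character(sample_info))
    sample_info <- read_sample_info(sample_info)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- origin analysis --------------------------------------------
  matches <- match_metabolites(metab_table[, c("name", "kegg_id",
                                               "hmdb_id")], kb)
  calls <- classify_origins(matches, kb)
  write_report(calls, out_dir, "origin_calls.tsv")
  write_report(category_counts(calls), out_dir, "category_counts.tsv")

  # ---- pretreatment + differential analysis ----------------------
  metab_vals <- metab_table[, c(1, 4:ncol(metab_table))]
  metab_imp <- impute_missing(metab_vals, method = impute_method,
                              seed = seed)
  metab_norm <- normalize_abundance(metab_imp, method = normalize_method)
  diff_met <- differential_analysis(metab_norm, sample_info, test = test,
                                    alpha = alpha)
  diff_met$entry_id <- calls$entry_id[match(diff_met$feature_id,
                                            calls$query_name)]
  write_report(diff_met, out_dir, "differential_metabolites.tsv")

  taxa_rank <- aggregate_taxa(taxa_table, rank = corr_rank)
  taxa_norm <- normalize_abundance(taxa_rank, method = "percentage")
  diff_taxa <- differential_analysis(taxa_norm, sample_info, test = test,
                                     alpha = alpha)
  write_report(diff_taxa, out_dir, "differential_taxa.tsv")

  # ---- origin-scoped enrichment of differential metabolites -------
  diff_calls <- calls[calls$query_name %in%
                        diff_met$feature_id[diff_met$significant] &
                        !is.na(calls$entry_id), ]
  mpea <- NULL
  if (nrow(diff_calls) > 0) {
    mpea <- mpea_all_scopes(diff_calls, kb, host_org, alpha)
    for (scope in names(mpea))
      if (!is.null(mpea[[scope]]))
        write_report(mpea[[scope]], out_dir,
                     paste0("mpea_", scope, ".tsv"))
    origin_sets <- purrr::compact(
      mpea[c("host", "microbiota", "cometabolism")])
    if (length(origin_sets) >= 2) {
      venn <- pathway_overlap(purrr::map(origin_sets, function(m)
        m$pathway_id[m$significant]))
      write_report(venn, out_dir, "pathway_overlap.tsv")
    }
  }

  # ---- correlation -------------------------------------------------
  correlations <- correlate(metab_norm, taxa_table, method = corr_method,
                            rank = corr_rank, alpha = alpha, seed = seed)
  write_report(correlations, out_dir,
               paste0("correlation_", corr_rank, ".tsv"))

  # ---- networks ----------------------------------------------------
  graphs <- list()
  summaries <- list()
  if (!is.null(mpea)) {
    graphs <- sankey_for_significant(
      mpea[c("host", "microbiota", "cometabolism")], diff_calls$entry_id,
      kb, diff_results = diff_met, correlations = correlations,
      alpha = alpha, out_dir = out_dir, variants = c("bio", "sta"))
    for (origin in c("host", "microbiota", "cometabolism")) {
      m <- mpea[[origin]]
      if (is.null(m) || !any(m$significant)) next
      net <- build_summary_network(origin, m, diff_met, correlations, kb,
                                   diff_taxa = diff_taxa,
                                   p_threshold = summary_p)
      base <- file.path(out_dir, paste0("summary_", origin))
      export_network(net, paste0(base, ".json"), "json")
      export_network(net, paste0(base, ".graphml"), "graphml")
      export_network(net, paste0(base, ".html"), "html")
      summaries[[origin]] <- net
    }
  }
  run_manifest(out_dir, "dmoa",
               list(host_org = host_org, impute_method = impute_method,
                    normalize_method = normalize_method, test = test,
                    alpha = alpha, corr_method = corr_method,
                    corr_rank = corr_rank, summary_p = summary_p,
                    seed = seed), kb)
  invisible(list(origin_calls = calls, diff_metabolites = diff_met,
                 diff_taxa = diff_taxa, mpea = mpea,
                 correlations = correlations, sankey = graphs,
                 summaries = summaries))
}
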