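# Microbe-metabolite association at a chosen taxonomic rank.

#' Parse prefixed lineage strings into rank columns
#'
#' Accepts the common `p__Phylum|c__Class|...|s__Species` form with `|` or
#' `;` separators, with or without rank prefixes (unprefixed fields are
#' assigned to ranks in order phylum..species). Missing interior ranks
#' become the explicit `"unclassified"` placeholder.
#'
#' @param x character vector of lineage strings.
#' @return tibble with columns `phylum`, `class`, `order`, `family`,
#'   `genus`, `species`.
#' @export
#' @examples
#' parse_lineage("p__Firmicutes|c__Clostridia|o__Eubacteriales")
parse_lineage <- function(x) {
  parts <- strsplit(as.character(x), "[|;]")
  rows <- purrr::map(parts, function(p) {
    p <- trimws(p)
    p <- p[p != ""]
    out <- stats::setNames(rep(MISSING_RANK, 6), TAXONOMY_RANKS)
    prefixed <- grepl("^[pcofgs]__", p)
    for (fld in p[prefixed]) {
      rk <- names(RANK_PREFIXES)[RANK_PREFIXES == substr(fld, 1, 1)]
      val <- sub("^[pcofgs]__", "", fld)
      if (length(rk) == 1 && val != "") out[rk] <- val
    }
    un <- p[!prefixed]
    if (length(un) > 0)
      out[seq_len(min(6, length(un)))] <- un[seq_len(min(6, length(un)))]
    out
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# Canonical lineage string truncated at `rank`.
lineage_string <- function(lineage_tbl, rank) {
  keep <- TAXONOMY_RANKS[seq_len(match(rank, TAXONOMY_RANKS))]
  apply(lineage_tbl[, keep, drop = FALSE], 1, function(r)
    paste(paste0(RANK_PREFIXES[keep], "__", r), collapse = "|"))
}

#' Aggregate a species-level taxa table to a coarser rank
#'
#' Child abundances are summed into their ancestor taxon at the requested
#' rank. With `drop_unclassified = TRUE`, children whose label at the
#' requested rank is the `"unclassified"` placeholder are excluded from
#' the parent sums instead of forming their own feature.
#'
#' @param taxa_table abundance tibble whose feature ids are lineage
#'   strings (see [parse_lineage()]).
#' @param rank target rank, one of phylum..species.
#' @param drop_unclassified drop children unclassified at `rank`.
#' @return abundance tibble whose feature ids are lineage strings
#'   truncated at `rank`.
#' @export
aggregate_taxa <- function(taxa_table, rank = "genus",
                           drop_unclassified = FALSE) {
  rank <- match.arg(rank, TAXONOMY_RANKS)
  parts <- abundance_parts(taxa_table)
  lin <- parse_lineage(rownames(parts$mat))
  key <- lineage_string(lin, rank)
  keep <- rep(TRUE, length(key))
  if (drop_unclassified)
    keep <- lin[[rank]] != MISSING_RANK
  mat <- parts$mat[keep, , drop = FALSE]
  agg <- rowsum(mat, group = key[keep], reorder = TRUE)
  out <- dplyr::bind_cols(
    tibble::tibble(taxon = rownames(agg)),
    tibble::as_tibble(agg))
  names(out)[1] <- names(taxa_table)[1]
  out
}

cor_pair <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(coefficient = 0, p_value = 1, degenerate = TRUE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(coefficient = unname(ct$estimate), p_value = ct$p.value,
       degenerate = FALSE)
}

#' Correlate microbial taxa with metabolites
#'
#' Computes a coefficient and two-sided p-value for every taxon x
#' metabolite pair over the samples shared by the two tables (aligned by
#' sample id). Spearman (default) uses average ranks for ties with the
#' t-approximation p-value; Pearson uses the usual t test; `mic` uses the
#' approximate maximal information coefficient of [mic_score()] with a
#' seeded permutation p-value. Pairs in which either vector is constant
#' are degenerate: coefficient 0, p = 1, flagged.
#'
#' @param metab_table metabolite abundance tibble (complete; feature ids in
#'   the first column — extra id columns such as kegg_id/hmdb_id are
#'   allowed and ignored).
#' @param taxa_table species-level taxa abundance tibble; aggregated to
#'   `rank` by [aggregate_taxa()] before correlating.
#' @param method `"spearman"`, `"pearson"` or `"mic"`.
#' @param rank taxonomic rank at which to correlate.
#' @param alpha significance level for the `significant` flag.
#' @param n_perm permutations for the MIC p-value.
#' @param seed seed for the MIC permutations.
#' @return tibble of class `correlation_table`: `rank`, `taxon`,
#'   `metabolite`, `method`, `coefficient`, `p_value`, `significant`,
#'   `degenerate`; attribute `n_samples` records the aligned sample count.
#' @export
correlate <- function(metab_table, taxa_table,
                      method = c("spearman", "pearson", "mic"),
                      rank = "genus", alpha = 0.05, n_perm = 200,
                      seed = 1L) {
  method <- match.arg(method)
  rank <- match.arg(rank, TAXONOMY_RANKS)
  mp <- abundance_parts(metab_table)
  taxa <- aggregate_taxa(taxa_table, rank)
  tp <- abundance_parts(taxa)
  shared <- intersect(colnames(mp$mat), colnames(tp$mat))
  n_all <- max(ncol(mp$mat), ncol(tp$mat))
  if (length(shared) < 3)
    stop_input("need at least 3 shared samples, got ", length(shared))
  if (length(shared) < n_all / 2)
    warning("more than half of the samples do not overlap between tables",
            call. = FALSE)
  mm <- mp$mat[, shared, drop = FALSE]
  tm <- tp$mat[, shared, drop = FALSE]
  if (anyNA(mm) || anyNA(tm))
    stop_input("correlation requires complete tables; impute first")
  grid <- tidyr::expand_grid(taxon = rownames(tm),
                             metabolite = rownames(mm))
  stats_list <- purrr::map(seq_len(nrow(grid)), function(idx) {
    x <- tm[grid$taxon[idx], ]
    y <- mm[grid$metabolite[idx], ]
    if (method == "mic") {
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(list(coefficient = 0, p_value = 1, degenerate = TRUE))
      s <- mic_score(x, y)
      p <- with_seed(derive_seed(seed, idx), {
        perms <- vapply(seq_len(n_perm),
                        function(i) mic_score(x, sample(y)), numeric(1))
        (sum(perms >= s) + 1) / (n_perm + 1)
      })
      list(coefficient = s, p_value = p, degenerate = FALSE)
    } else {
      cor_pair(x, y, method)
    }
  })
  out <- grid |>
    dplyr::mutate(
      rank = rank,
      method = method,
      coefficient = purrr::map_dbl(stats_list, "coefficient"),
      p_value = purrr::map_dbl(stats_list, "p_value"),
      degenerate = purrr::map_lgl(stats_list, "degenerate"),
      significant = .data$p_value <= alpha & !.data$degenerate) |>
    dplyr::select("rank", "taxon", "metabolite", "method", "coefficient",
                  "p_value", "significant", "degenerate")
  attr(out, "n_samples") <- length(shared)
  attr(out, "alpha") <- alpha
  class(out) <- c("correlation_table", class(out))
  out
}

#' Keep only significant correlation pairs
#'
#' @param table a [correlate()] result.
#' @param alpha p-value threshold.
#' @return the filtered `correlation_table` (the `significant` flag is
#'   recomputed at `alpha`).
#' @export
filter_significant <- function(table, alpha = 0.05) {
  out <- table[table$p_value <= alpha & !table$degenerate, , drop = FALSE]
  out$significant <- TRUE
  attr(out, "n_samples") <- attr(table, "n_samples")
  attr(out, "alpha") <- alpha
  class(out) <- unique(c("correlation_table", class(out)))
  out
}

#' Approximate maximal information coefficient
#'
#' A grid-search approximation of MIC: for every grid shape (i, j) with
#' `i * j <= B(n) = n^alpha_exponent` and `2 <= i, j <= max_clumps`, both
#' variables are partitioned into equal-frequency bins (i bins on x,
#' j bins on y), the mutual information of the induced contingency table
#' is computed in bits and normalized by `log2(min(i, j))`, and the
#' maximum over shapes is returned. The equipartition search is a
#' deterministic, documented approximation of the full dynamic-programming
#' MIC optimization: it saturates at 1 for noiseless functional
#' relationships and stays near 0 for independent inputs, but can
#' underestimate MIC for relationships whose optimal partition is far from
#' equal-frequency.
#'
#' @param x,y numeric vectors, at least 8 paired samples.
#' @param alpha_exponent grid-budget exponent, `B(n) = n^alpha_exponent`.
#' @param max_clumps cap on bins per axis.
#' @return score in \\[0, 1\\]; symmetric in x and y.
#' @export
mic_score <- function(x, y, alpha_exponent = 0.6, max_clumps = 15) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  n <- length(x)
  if (n < 8)
    stop_input("MIC needs at least 8 paired samples; ",
               "use Spearman for smaller n")
  budget <- max(4, floor(n ^ alpha_exponent))
  bin_ids <- function(v, nb) {
    # equal-frequency bins; ties share the bin of their average rank
    ceiling(rank(v, ties.method = "average") * nb / (n + 0.5))
  }
  best <- 0
  for (i in 2:min(max_clumps, floor(budget / 2))) {
    for (j in 2:min(max_clumps, floor(budget / i))) {
      tab <- table(bin_ids(x, i), bin_ids(y, j))
      pxy <- tab / n
      px <- rowSums(pxy)
      py <- colSums(pxy)
      nz <- pxy > 0
      mi <- sum(pxy[nz] * log2(pxy[nz] / outer(px, py)[nz]))
      best <- max(best, mi / log2(min(i, j)))
    }
  }
  min(best, 1)
}
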