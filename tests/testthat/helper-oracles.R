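# Independent brute-force oracles used to check the implementation by a
# second route. These deliberately avoid the code paths they verify.

# Union-find over record indices: components under the merge relation
# (shared kegg id, shared hmdb id, or same normalized formula + a shared
# normalized name/synonym).
oracle_merge_components <- function(records) {
  n <- nrow(records)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  union_ <- function(i, j) {
    ri <- find(i)
    rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  norm <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
  names_of <- function(i) {
    v <- c(records$name[i],
           strsplit(records$synonyms[i], ";", fixed = TRUE)[[1]])
    setdiff(norm(v), "")
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    share_kegg <- records$kegg_id[i] != "" &&
      records$kegg_id[i] == records$kegg_id[j]
    share_hmdb <- records$hmdb_id[i] != "" &&
      records$hmdb_id[i] == records$hmdb_id[j]
    share_formula_name <- norm(records$formula[i]) != "" &&
      norm(records$formula[i]) == norm(records$formula[j]) &&
      length(intersect(names_of(i), names_of(j))) > 0
    if (share_kegg || share_hmdb || share_formula_name) union_(i, j)
  }
  vapply(seq_len(n), find, integer(1))
}

# Exhaustive upper-tail hypergeometric probability by pmf summation with
# plain binomial coefficients (no log-gamma shortcuts).
oracle_hyper_upper <- function(q, m, n, k) {
  i <- q:min(m, k)
  sum(choose(m, i) * choose(n, k - i)) / choose(m + n, k)
}

# Truth-table origin classification, written as a direct transcription of
# the category definitions (no precedence short-circuiting).
oracle_origin <- function(tags) {
  has <- function(t) t %in% tags
  microbial <- has("archaea") || has("fungi") || has("bacteria")
  if (has("mammal") && microbial) return("Co-Metabolism")
  if (has("mammal")) return("Host")
  if (microbial) return("Microbiota")
  if (has("food_plant")) return("Food")
  if (has("drug")) return("Drug")
  if (has("toxin_pollutant")) return("Environment")
  "Unknown"
}

# Distinct-species counts beneath every adjacent-rank branch of a lineage
# table (one row per species), tallied by explicit looping.
oracle_lineage_widths <- function(lin, species_ids) {
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  out <- list()
  for (b in seq_len(5)) {
    key <- paste(lin[[ranks[b]]], lin[[ranks[b + 1]]], sep = " -> ")
    for (k in unique(key)) {
      out[[paste0(ranks[b], "|", k)]] <-
        length(unique(species_ids[key == k]))
    }
  }
  out
}

# Small random record set for merge fuzzing.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    kegg_pool <- c(sprintf("C%05d", 1:6), rep("", 4))
    hmdb_pool <- c(sprintf("HMDB%04d", 1:6), rep("", 4))
    name_pool <- c(paste("compound", letters[1:8]), "")
    tibble::tibble(
      source_db = sample(c("kegg", "hmdb", "chebi"), n, replace = TRUE),
      native_id = sprintf("N%03d", seq_len(n)),
      kegg_id = sample(kegg_pool, n, replace = TRUE),
      hmdb_id = sample(hmdb_pool, n, replace = TRUE),
      formula = sample(c("C6H12O6", "C2H6O", "CH4", ""), n, replace = TRUE),
      name = sample(name_pool, n, replace = TRUE),
      synonyms = sample(c("", "alias x", "alias y;alias z"), n,
                        replace = TRUE),
      origin_tags = sample(c("", "mammal", "bacteria", "mammal;bacteria",
                             "drug"), n, replace = TRUE))
  })
}

tiny_usable <- function(records) {
  records[records$kegg_id != "" | records$hmdb_id != "" |
            records$name != "", , drop = FALSE]
}
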