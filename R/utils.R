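# Internal helpers shared across modules.

ORIGIN_TAGS <- c("mammal", "archaea", "fungi", "bacteria",
                 "food_plant", "drug", "toxin_pollutant")

MICROBIAL_TAGS <- c("archaea", "fungi", "bacteria")

ORIGIN_CATEGORIES <- c("Host", "Microbiota", "Co-Metabolism",
                       "Food", "Drug", "Environment", "Unknown")

TAXONOMY_RANKS <- c("phylum", "class", "order", "family", "genus", "species")

RANK_PREFIXES <- c(phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")

MISSING_RANK <- "unclassified"

#' Normalize a compound or taxon name for matching
#'
#' Case-folds and strips whitespace, hyphens, parentheses and other
#' punctuation so that typographic variants of the same name
#' (e.g. "N-Acetyl-L-phenylalanine" vs "n acetyl L phenylalanine")
#' compare equal. Used for metabolite synonym matching, record merging
#' and taxon-name matching throughout the package.
#'
#' @param x character vector of names.
#' @return character vector of normalized keys; empty strings stay empty.
#' @export
#' @examples
#' normalize_name(c("N-Acetyl-L-phenylalanine", "Phenyl lactate (PLA)"))
normalize_name <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", "", x)
  x[is.na(x)] <- ""
  x
}

# Split a ";"-joined set column into a list of sorted unique elements.
split_set <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) sort(unique(v[v != ""])))
}

# Join a set into the canonical on-disk form (sorted, ";"-separated).
join_set <- function(x) {
  vapply(x, function(v) paste(sort(unique(v[!is.na(v) & v != ""])),
                              collapse = ";"), character(1))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream-specific 31-bit seed from a base seed, so independent
# generators (metabolites, taxa, missingness, ...) never share a stream.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
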