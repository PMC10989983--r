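#' Build an origin-scoped reference pathway library
#'
#' Pathway enrichment is only meaningful against a reference universe that
#' matches the origin of the differential metabolites. The library
#' restricts the knowledge base's pathways to those carried by the
#' organisms of the requested scope:
#'
#' * `host`: pathways occurring in the selected host organism;
#' * `microbiota`: pathways occurring in any microbial organism
#'   (bacteria, archaea or fungi);
#' * `cometabolism`: the union of the two — its universe is by
#'   construction the host universe united with the microbiota universe;
#' * `all_host` / `all_cometabolism`: the same pathway sets and universes
#'   as `host` / `cometabolism`, but intended for the pooled comparison
#'   modes in which ALL differential metabolites (not an origin subset)
#'   are tested against one reference.
#'
#' @param kb a [metab_kb()].
#' @param scope one of `"host"`, `"microbiota"`, `"cometabolism"`,
#'   `"all_host"`, `"all_cometabolism"`.
#' @param host_org organism code of the host (required for host-involving
#'   scopes).
#' @return object of class `reference_library`: list with `scope`,
#'   `pathways` (tibble `pathway_id`, `name`), `members` (tibble
#'   `pathway_id`, `entry_id`) and `universe` (character vector of all
#'   member entry ids).
#' @export
build_reference_library <- function(kb,
                                    scope = c("host", "microbiota",
                                              "cometabolism", "all_host",
                                              "all_cometabolism"),
                                    host_org = NULL) {
  stopifnot(inherits(kb, "metab_kb"))
  scope <- match.arg(scope)
  base_scope <- sub("^all_", "", scope)
  orgs <- character(0)
  if (base_scope %in% c("host", "cometabolism")) {
    if (is.null(host_org) || !host_org %in% kb$organisms$org_code)
      stop_input("host_org must name an organism in the knowledge base")
    orgs <- host_org
  }
  if (base_scope %in% c("microbiota", "cometabolism")) {
    microbes <- kb$organisms$org_code[kb$organisms$kind %in% MICROBIAL_TAGS]
    if (length(microbes) == 0)
      stop_input("knowledge base contains no microbial organisms")
    orgs <- c(orgs, microbes)
  }
  pw_ids <- sort(unique(
    kb$pathway_organisms$pathway_id[kb$pathway_organisms$org_code %in% orgs]))
  if (length(pw_ids) == 0)
    stop_input("no pathway occurs in any organism of scope '", scope, "'")
  members <- kb$pathway_members |>
    dplyr::filter(.data$pathway_id %in% pw_ids) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$pathway_id, .data$entry_id)
  structure(
    list(scope = scope,
         pathways = dplyr::filter(kb$pathways, .data$pathway_id %in% pw_ids),
         members = members,
         universe = sort(unique(members$entry_id))),
    class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat("<reference_library>", x$scope, "scope:",
      nrow(x$pathways), "pathways,", length(x$universe),
      "universe metabolites\n")
  invisible(x)
}

#' Upper-tail hypergeometric p-value for pathway enrichment
#'
#' The probability of drawing at least `q` pathway members when `k`
#' differential metabolites are drawn without replacement from a universe
#' of `m` pathway members and `n` non-members, i.e. `P(X >= q)` with
#' `X ~ Hypergeometric(m + n, m, k)`. Computed as the upper tail
#' `phyper(q - 1, m, n, k, lower.tail = FALSE)` directly, which avoids the
#' catastrophic cancellation of `1 - P(X <= q - 1)` for small p.
#'
#' @param q number of differential metabolites matched in the pathway.
#' @param m total metabolites in the pathway (within scope).
#' @param n metabolites in the other pathways of the scope.
#' @param k total differential metabolites mapped to the universe.
#' @return p-value(s) in (0, 1]; arguments recycle as usual.
#' @export
#' @examples
#' hypergeom_pvalue(2, 3, 7, 5)   # exact: 0.5
hypergeom_pvalue <- function(q, m, n, k) {
  bad <- is.na(q) | is.na(m) | is.na(n) | is.na(k) |
    q < 0 | m < 0 | n < 0 | k < 0 | q > pmin(m, k) | k > m + n
  if (any(bad))
    stop_input("invalid hypergeometric counts (need 0 <= q <= min(m, k), ",
               "k <= m + n)")
  stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
}

#' Origin-based metabolic pathway enrichment analysis
#'
#' Tests every pathway of an origin-scoped reference library for
#' over-representation of the differential metabolites, using the
#' upper-tail hypergeometric test of [hypergeom_pvalue()]. Differential
#' metabolites that do not map to the library universe are excluded from
#' `k` (and reported via the `"unmapped"` attribute); only pathways with
#' at least one hit are returned.
#'
#' @param diff_ids character vector of differential metabolite entry ids.
#' @param library a [build_reference_library()] result.
#' @param alpha significance level for the `significant` flag (raw p by
#'   default; set `adjust = "BH"` to threshold the adjusted column).
#' @param adjust `"none"` or `"BH"`.
#' @return tibble of class `mpea_result`, sorted by ascending p then
#'   pathway id: `pathway_id`, `name`, `q`, `m`, `n`, `k`, `p_value`,
#'   `p_adj`, `significant`, `hit_ids` (`;`-joined). Attributes: `scope`,
#'   `k`, `universe_size`, `unmapped`.
#' @export
run_mpea <- function(diff_ids, library, alpha = 0.05,
                     adjust = c("none", "BH")) {
  stopifnot(inherits(library, "reference_library"))
  adjust <- match.arg(adjust)
  diff_ids <- unique(as.character(diff_ids))
  if (length(diff_ids) == 0) stop_input("diff_ids must be non-empty")
  mapped <- intersect(diff_ids, library$universe)
  k <- length(mapped)
  unmapped <- setdiff(diff_ids, library$universe)
  empty <- tibble::tibble(pathway_id = character(), name = character(),
                          q = integer(), m = integer(), n = integer(),
                          k = integer(), p_value = numeric(),
                          p_adj = numeric(), significant = logical(),
                          hit_ids = character())
  if (k == 0) {
    warning("none of the differential metabolites map to the '",
            library$scope, "' universe", call. = FALSE)
    out <- empty
  } else {
    universe_size <- length(library$universe)
    out <- library$members |>
      dplyr::group_by(.data$pathway_id) |>
      dplyr::summarise(
        m = dplyr::n(),
        q = sum(.data$entry_id %in% mapped),
        hit_ids = join_set(list(.data$entry_id[.data$entry_id %in% mapped])),
        .groups = "drop") |>
      dplyr::filter(.data$q >= 1) |>
      dplyr::mutate(n = universe_size - .data$m,
                    k = k,
                    p_value = hypergeom_pvalue(.data$q, .data$m,
                                               .data$n, .data$k)) |>
      dplyr::left_join(library$pathways, by = "pathway_id") |>
      dplyr::arrange(.data$p_value, .data$pathway_id) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p_value, "BH"),
                    significant = (if (adjust == "BH") .data$p_adj
                                   else .data$p_value) <= alpha) |>
      dplyr::select("pathway_id", "name", "q", "m", "n", "k",
                    "p_value", "p_adj", "significant", "hit_ids")
  }
  attr(out, "scope") <- library$scope
  attr(out, "k") <- k
  attr(out, "universe_size") <- length(library$universe)
  attr(out, "unmapped") <- unmapped
  attr(out, "alpha") <- alpha
  class(out) <- c("mpea_result", class(out))
  out
}

#' Overlap of enriched pathway sets across origins
#'
#' Computes the disjoint Venn regions of 2 or more pathway-id sets (e.g.
#' the significant pathways of the Host, Microbiota and Co-Metabolism
#' scopes): each pathway is assigned to exactly one region labelled by the
#' `&`-joined names of the sets containing it, so region counts sum to the
#' size of the union and per-set totals are recovered by summing the
#' regions naming that set.
#'
#' @param sets named list of character vectors (or of `mpea_result`
#'   tibbles, whose `pathway_id` columns are used).
#' @return tibble `region`, `n`, including empty regions (n = 0) for every
#'   combination of sets.
#' @export
pathway_overlap <- function(sets) {
  if (length(sets) < 2) stop_input("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop_input("sets must be named")
  sets <- purrr::map(sets, function(s) {
    if (is.data.frame(s)) unique(s$pathway_id) else unique(as.character(s))
  })
  ids <- unique(unlist(sets))
  member <- matrix(vapply(sets, function(s) ids %in% s,
                          logical(length(ids))),
                   nrow = length(ids))
  region_of <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  combos <- unlist(lapply(seq_along(sets), function(sz)
    utils::combn(names(sets), sz, paste, collapse = "&", simplify = FALSE)))
  tibble::tibble(
    region = combos,
    n = unname(vapply(combos, function(cb) sum(region_of == cb),
                      integer(1))))
}
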