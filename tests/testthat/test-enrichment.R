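# Origin-scoped reference libraries and hypergeometric enrichment.

test_that("the worked hypergeometric example gives exactly 0.5", {
  # P(X >= 2) for population 10 = 3 + 7, 5 draws, by exhaustive pmf sum
  expect_equal(oracle_hyper_upper(2, 3, 7, 5), 0.5)
  expect_equal(hypergeom_pvalue(2, 3, 7, 5), 0.5)
  expect_equal(hypergeom_pvalue(0, 5, 95, 10), 1)
})

test_that("upper-tail p matches the pmf-summation oracle on a grid", {
  withr::with_seed(14, {
    cases <- tibble::tibble(
      m = sample(1:30, 120, replace = TRUE),
      n = sample(0:30, 120, replace = TRUE),
      k = NA_integer_, q = NA_integer_)
    cases$k <- vapply(seq_len(120), \(i)
      sample(0:(cases$m[i] + cases$n[i]), 1), integer(1))
    cases$q <- vapply(seq_len(120), \(i)
      sample(0:min(cases$m[i], cases$k[i]), 1), integer(1))
  })
  got <- hypergeom_pvalue(cases$q, cases$m, cases$n, cases$k)
  want <- vapply(seq_len(nrow(cases)), \(i)
    oracle_hyper_upper(cases$q[i], cases$m[i], cases$n[i], cases$k[i]),
    numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  # and p is non-increasing in q for fixed (m, n, k)
  ps <- hypergeom_pvalue(0:5, 8, 12, 5)
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("invalid counts are rejected", {
  expect_error(hypergeom_pvalue(4, 3, 7, 5), "invalid")
  expect_error(hypergeom_pvalue(1, 3, 1, 5), "invalid")
})

test_that("scope libraries match a brute-force organism-pathway scan", {
  kb <- generate_kb(fixture_spec(seed = 12))
  microbial <- kb$organisms$org_code[
    kb$organisms$kind %in% c("bacteria", "archaea", "fungi")]
  for (scope in c("host", "microbiota", "cometabolism")) {
    lib <- build_reference_library(kb, scope, host_org = "hsa")
    want_orgs <- switch(scope, host = "hsa", microbiota = microbial,
                        cometabolism = c("hsa", microbial))
    want_pw <- sort(unique(kb$pathway_organisms$pathway_id[
      kb$pathway_organisms$org_code %in% want_orgs]))
    expect_setequal(lib$pathways$pathway_id, want_pw)
    expect_setequal(lib$universe,
                    unique(kb$pathway_members$entry_id[
                      kb$pathway_members$pathway_id %in% want_pw]))
  }
  host_u <- build_reference_library(kb, "host", "hsa")$universe
  micro_u <- build_reference_library(kb, "microbiota")$universe
  co_u <- build_reference_library(kb, "cometabolism", "hsa")$universe
  expect_setequal(co_u, union(host_u, micro_u))
})

test_that("a bacteria-only pathway is present in the microbiota library and absent from host", {
  kb <- generate_kb(fixture_spec(seed = 12))
  bo <- kb$pathways$pathway_id[grepl("bacteria_only", kb$pathways$name)][1]
  expect_true(bo %in%
                build_reference_library(kb, "microbiota")$pathways$pathway_id)
  expect_false(bo %in%
                 build_reference_library(kb, "host", "hsa")$pathways$pathway_id)
})

test_that("an empty scope errors", {
  kb <- phenylalanine_kb()
  expect_error(build_reference_library(kb, "host", host_org = "none"),
               "host_org")
})

test_that("enrichment results are self-consistent and sorted", {
  kb <- generate_kb(fixture_spec(seed = 12))
  lib <- build_reference_library(kb, "cometabolism", "hsa")
  withr::with_seed(7, {
    diff_ids <- sample(lib$universe, 6)
  })
  res <- run_mpea(diff_ids, lib)
  expect_gt(nrow(res), 0)
  expect_true(all(res$q >= 1))
  expect_equal(res$p_value,
               vapply(seq_len(nrow(res)), \(i) oracle_hyper_upper(
                 res$q[i], res$m[i], res$n[i], res$k[i]), numeric(1)),
               tolerance = 1e-10)
  expect_false(is.unsorted(res$p_value))
  expect_equal(res$q, lengths(strsplit(res$hit_ids, ";")))
  expect_equal(unique(res$k), length(intersect(diff_ids, lib$universe)))
})

test_that("a fully differential pathway ranks first in its scope", {
  kb <- generate_kb(fixture_spec(seed = 12))
  lib <- build_reference_library(kb, "microbiota")
  bo <- kb$pathways$pathway_id[grepl("bacteria_only", kb$pathways$name)][1]
  members <- lib$members$entry_id[lib$members$pathway_id == bo]
  res <- run_mpea(members, lib)
  expect_equal(res$pathway_id[1], bo)
  expect_equal(min(res$p_value), res$p_value[res$pathway_id == bo])
})

test_that("adding a non-member metabolite never decreases any pathway's p", {
  kb <- generate_kb(fixture_spec(seed = 12))
  lib <- build_reference_library(kb, "cometabolism", "hsa")
  withr::with_seed(8, {
    diff_ids <- sample(lib$universe, 5)
  })
  base <- run_mpea(diff_ids, lib)
  extra_pool <- setdiff(lib$universe, diff_ids)
  for (pw in base$pathway_id) {
    non_member <- setdiff(extra_pool,
                          lib$members$entry_id[lib$members$pathway_id == pw])
    if (length(non_member) == 0) next
    grown <- run_mpea(c(diff_ids, non_member[1]), lib)
    if (pw %in% grown$pathway_id)
      expect_gte(grown$p_value[grown$pathway_id == pw] + 1e-12,
                 base$p_value[base$pathway_id == pw])
  }
})

test_that("unmappable differential metabolites are excluded from k and reported", {
  kb <- phenylalanine_kb()
  lib <- build_reference_library(kb, "microbiota")
  res <- run_mpea(c("MB00003", "not-an-entry"), lib)
  expect_equal(attr(res, "k"), 1)
  expect_equal(attr(res, "unmapped"), "not-an-entry")
  expect_warning(run_mpea("still-not-an-entry", lib), "map")
})

test_that("venn regions follow set algebra", {
  expect_equal(pathway_overlap(list(a = "P1", b = "P2")),
               tibble::tibble(region = c("a", "b", "a&b"), n = c(1L, 1L, 0L)))
  same <- pathway_overlap(list(a = c("P1", "P2"), b = c("P1", "P2")))
  expect_equal(same$n[same$region == "a&b"], 2L)
  expect_equal(sum(same$n[same$region %in% c("a", "b")]), 0L)
  withr::with_seed(5, {
    sets <- list(x = sample(LETTERS, 10), y = sample(LETTERS, 8),
                 z = sample(LETTERS, 12))
  })
  venn <- pathway_overlap(sets)
  expect_equal(sum(venn$n), length(unique(unlist(sets))))
  # per-set totals recovered by summing the regions naming that set
  for (nm in names(sets)) {
    in_region <- vapply(strsplit(venn$region, "&", fixed = TRUE),
                        \(r) nm %in% r, logical(1))
    expect_equal(sum(venn$n[in_region]), length(unique(sets[[nm]])))
  }
})
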