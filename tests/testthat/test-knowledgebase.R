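# Metabolite source-record merging, matching, origin classification and
# bundle persistence.

rec <- function(source_db = "kegg", native_id = "X", kegg_id = "",
                hmdb_id = "", formula = "", name = "", synonyms = "",
                origin_tags = "") {
  tibble::tibble(source_db = source_db, native_id = native_id,
                 kegg_id = kegg_id, hmdb_id = hmdb_id, formula = formula,
                 name = name, synonyms = synonyms,
                 origin_tags = origin_tags)
}

test_that("records sharing a KEGG id merge into one entry with unioned synonyms", {
  recs <- dplyr::bind_rows(
    rec(kegg_id = "C00079", name = "L-Phenylalanine", synonyms = "Phe",
        origin_tags = "bacteria"),
    rec(source_db = "hmdb", kegg_id = "C00079", hmdb_id = "HMDB0000159",
        name = "Phenylalanine", origin_tags = "mammal"))
  entries <- merge_sources(recs)
  expect_equal(nrow(entries), 1)
  expect_setequal(strsplit(entries$names, ";")[[1]],
                  c("L-Phenylalanine", "Phe", "Phenylalanine"))
  expect_equal(entries$origin_tags, "bacteria;mammal")
  expect_equal(entries$kegg_ids, "C00079")
  expect_equal(entries$hmdb_ids, "HMDB0000159")
})

test_that("records with no shared evidence stay separate", {
  recs <- dplyr::bind_rows(
    rec(kegg_id = "C00001", name = "water", formula = "H2O"),
    rec(kegg_id = "C00002", name = "ATP", formula = "C10H16N5O13P3"))
  expect_equal(nrow(merge_sources(recs)), 2)
})

test_that("merging is transitive across different id types", {
  recs <- dplyr::bind_rows(
    rec(native_id = "A", kegg_id = "C00001", name = "a"),
    rec(native_id = "B", kegg_id = "C00001", hmdb_id = "HMDB0001"),
    rec(native_id = "C", hmdb_id = "HMDB0001", name = "c"))
  expect_equal(nrow(merge_sources(recs)), 1)
})

test_that("merge components match a union-find oracle on randomized record sets", {
  for (seed in 1:40) {
    n <- 5 + seed %% 16
    records <- tiny_usable(random_records(n, seed))
    if (nrow(records) < 2) next
    entries <- suppressWarnings(merge_sources(records))
    comp <- oracle_merge_components(records)
    expect_equal(nrow(entries), length(unique(comp)),
                 label = paste("seed", seed))
  }
})

test_that("records without any identifier are rejected individually, not fatally", {
  recs <- dplyr::bind_rows(
    rec(kegg_id = "C00001", name = "water"),
    rec(formula = "C2H6O"))  # formula alone is not an identifier
  expect_warning(entries <- merge_sources(recs), "rejected")
  expect_equal(nrow(entries), 1)
  expect_equal(nrow(attr(entries, "rejected")), 1)
  expect_match(attr(entries, "rejected")$reason, "no usable identifier")
})

test_that("deduplication is idempotent", {
  for (seed in c(2, 11, 23)) {
    records <- tiny_usable(random_records(12, seed))
    entries <- suppressWarnings(merge_sources(records))
    again <- merge_sources(entries_as_records(entries))
    expect_equal(nrow(again), nrow(entries), label = paste("seed", seed))
  }
})

test_that("matching honors KEGG > HMDB > name precedence and synonyms", {
  kb <- phenylalanine_kb()
  hits <- match_metabolites(
    tibble::tibble(name = c("", "phenyl lactate", "nothing here"),
                   kegg_id = c("C00180", "", ""),
                   hmdb_id = c("", "", "")), kb)
  expect_equal(hits$entry_id, c("MB00003", "MB00004", NA))
  expect_equal(hits$matched_by, c("kegg", "name", NA))

  # HMDB beats name when the KEGG id is absent; checked against a linear
  # scan over all entries
  kb2 <- kb_from_entries(suppressWarnings(merge_sources(dplyr::bind_rows(
    rec(kegg_id = "C00001", hmdb_id = "HMDB0001", name = "alpha"),
    rec(kegg_id = "C00002", hmdb_id = "HMDB0002", name = "beta")))))
  q <- tibble::tibble(name = "alpha", kegg_id = "", hmdb_id = "HMDB0002")
  hit <- match_metabolites(q, kb2)
  scan <- kb2$entry_xrefs$entry_id[kb2$entry_xrefs$db == "hmdb" &
                                     kb2$entry_xrefs$xref_id == "HMDB0002"]
  expect_equal(hit$entry_id, scan)
  expect_equal(hit$matched_by, "hmdb")
})

test_that("conflicting KEGG/HMDB ids resolve by KEGG with a warning", {
  kb <- kb_from_entries(suppressWarnings(merge_sources(dplyr::bind_rows(
    rec(kegg_id = "C00001", name = "alpha"),
    rec(hmdb_id = "HMDB0002", name = "beta")))))
  q <- tibble::tibble(name = "", kegg_id = "C00001", hmdb_id = "HMDB0002")
  expect_warning(hit <- match_metabolites(q, kb), "conflict")
  expect_equal(hit$matched_by, "kegg")
  expect_equal(hit$note, "id_conflict")
})

test_that("origin classification reproduces the exhaustive truth table", {
  tags <- c("mammal", "archaea", "fungi", "bacteria", "food_plant",
            "drug", "toxin_pollutant")
  sets <- lapply(0:(2^7 - 1), function(mask)
    tags[bitwAnd(mask, 2^(0:6)) > 0])
  got <- as.character(origin_category(sets))
  want <- vapply(sets, oracle_origin, character(1))
  expect_equal(got, want)
})

test_that("co-metabolism calls are symmetric in which source gave which tag", {
  expect_equal(as.character(origin_category(list(c("mammal", "bacteria")))),
               as.character(origin_category(list(c("bacteria", "mammal")))))
  expect_equal(as.character(origin_category(list(c("mammal", "fungi")))),
               "Co-Metabolism")
})

test_that("every query gets exactly one category and counts partition the calls", {
  kb <- generate_kb(fixture_spec(seed = 5))
  withr::with_seed(99, {
    q <- tibble::tibble(
      name = c(sample(kb$entries$name, 40, replace = TRUE),
               sprintf("no such compound %d", 1:10)),
      kegg_id = "", hmdb_id = "")
  })
  calls <- classify_origins(match_metabolites(q, kb), kb)
  expect_equal(nrow(calls), 50)
  expect_false(anyNA(calls$category))
  counts <- category_counts(calls)
  expect_equal(sum(counts$n), 50)
  collapsed <- category_counts(calls, collapse_others = TRUE)
  expect_equal(sum(collapsed$n), 50)
  expect_equal(collapsed$n[collapsed$category == "Others"],
               sum(counts$n[counts$category %in%
                              c("Food", "Drug", "Environment")]))
})

test_that("unmatched queries are Unknown and an empty-evidence match is Unknown", {
  kb <- phenylalanine_kb()
  calls <- classify_origins(match_metabolites(
    tibble::tibble(name = "unobtainium", kegg_id = "", hmdb_id = ""), kb),
    kb)
  expect_equal(as.character(calls$category), "Unknown")
  expect_true(is.na(calls$entry_id))
})

test_that("knowledge-base bundle save -> load -> save is byte-identical", {
  kb <- generate_kb(fixture_spec(seed = 8))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_kb(kb, d1)
  write_kb(read_kb(d1), d2)
  for (f in list.files(d1)) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2, label = f)
  }
})

test_that("bundle validation rejects dangling references", {
  kb <- phenylalanine_kb()
  broken <- kb
  broken$pathway_members$entry_id[1] <- "MB99999"
  expect_error(validate_kb(broken), "unknown id")
})
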