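# Sankey construction, summary networks and serialization.

test_that("the phenylalanine pathway yields exactly its five differential reactions", {
  kb <- phenylalanine_kb()
  rxns <- reactions_for_pathway("map00360", phenylalanine_diff_ids(), kb)
  expect_equal(rxns$reaction_id,
               c("R00693", "R01370", "R01371", "R01424", "R06786"))
  expect_equal(reactions_for_pathway("map00360", "MB00007", kb)$reaction_id,
               "R09999")
  expect_equal(nrow(reactions_for_pathway("map00360", "no-hit", kb)), 0)
  expect_error(reactions_for_pathway("map99999", "MB00001", kb),
               "unknown pathway")
})

test_that("touched reactions equal a brute-force participant scan on random fixtures", {
  kb <- generate_kb(fixture_spec(seed = 20))
  withr::with_seed(30, {
    for (i in 1:5) {
      pw <- sample(kb$pathways$pathway_id, 1)
      diff_ids <- sample(kb$entries$entry_id, 5)
      got <- reactions_for_pathway(pw, diff_ids, kb)$reaction_id
      in_pw <- kb$reaction_pathways$reaction_id[
        kb$reaction_pathways$pathway_id == pw]
      want <- sort(unique(Filter(function(r) {
        parts <- kb$reaction_participants$entry_id[
          kb$reaction_participants$reaction_id == r]
        length(intersect(parts, diff_ids)) > 0
      }, in_pw)))
      expect_equal(got, want, label = paste("iter", i))
    }
  })
})

test_that("the R00693 Bio-Sankey has the expected metabolite and phylum structure", {
  kb <- phenylalanine_kb()
  g <- build_bio_sankey("R00693", kb)
  met_labels <- g$nodes$label[g$nodes$kind == "metabolite"]
  expect_setequal(met_labels,
                  c("L-Phenylalanine", "N-Acetyl-L-phenylalanine"))
  phyla <- g$nodes$label[g$nodes$kind == "phylum"]
  expect_setequal(phyla, c("Proteobacteria", "Firmicutes"))
  # both phyla link from the enzyme node
  enz <- g$nodes$node_id[g$nodes$kind == "enzyme"]
  expect_equal(g$nodes$label[g$nodes$kind == "enzyme"], "2.3.1.53")
  phylum_targets <- g$links$target[g$links$source == enz]
  expect_setequal(phylum_targets,
                  paste0("phylum:", c("Proteobacteria", "Firmicutes")))
})

test_that("a reaction with no lineage-bearing organisms keeps only metabolite and enzyme nodes", {
  kb <- phenylalanine_kb()
  g <- build_bio_sankey("R09999", kb)   # carried by eco only in kb
  expect_true(all(c("metabolite", "enzyme") %in% g$nodes$kind))
  kb2 <- kb
  kb2$reaction_organisms <- kb2$reaction_organisms[
    kb2$reaction_organisms$reaction_id != "R01370", ]
  g2 <- build_bio_sankey("R01370", kb2)
  expect_setequal(unique(g2$nodes$kind), c("metabolite", "enzyme"))
  expect_true(all(g2$links$width == 1))
})

test_that("band widths equal distinct-species counts from a lineage tally oracle", {
  kb <- phenylalanine_kb()
  for (rid in c("R00693", "R06786", "R01424")) {
    g <- build_bio_sankey(rid, kb)
    orgs <- dplyr::left_join(
      kb$reaction_organisms[kb$reaction_organisms$reaction_id == rid, ],
      kb$organisms, by = "org_code")
    want <- oracle_lineage_widths(orgs, orgs$org_code)
    lk <- tidy(g)
    tax <- lk[lk$source_kind %in%
                c("phylum", "class", "order", "family", "genus"), ]
    for (i in seq_len(nrow(tax))) {
      key <- paste0(tax$source_kind[i], "|", tax$source_label[i], " -> ",
                    tax$target_label[i])
      expect_equal(tax$width[i], want[[key]], label = key)
    }
  }
})

test_that("width is conserved across every taxonomy column boundary", {
  specs <- list(fixture_spec(seed = 31), fixture_spec(seed = 32))
  for (spec in specs) {
    kb <- generate_kb(spec)
    for (rid in kb$reactions$reaction_id) {
      g <- build_bio_sankey(rid, kb)
      n_species <- sum(g$nodes$kind == "species")
      if (n_species == 0) next
      lk <- tidy(g)
      for (src in c("phylum", "class", "order", "family", "genus")) {
        expect_equal(sum(lk$width[lk$source_kind == src]), n_species,
                     label = paste(rid, src))
      }
    }
  }
})

test_that("correlation overlay colors and emphasizes only significant taxa (bio)", {
  kb <- phenylalanine_kb()
  cors <- tibble::tibble(
    rank = "genus",
    taxon = c("p__Proteobacteria|c__Gammaproteobacteria|o__Enterobacterales|f__Enterobacteriaceae|g__Klebsiella",
              "p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Clostridiaceae|g__Clostridium"),
    metabolite = c("L-Phenylalanine", "N-Acetyl-L-phenylalanine"),
    method = "spearman",
    coefficient = c(0.8, -0.7),
    p_value = c(0.001, 0.2),
    significant = c(TRUE, FALSE),
    degenerate = FALSE)
  g <- build_bio_sankey("R00693", kb, correlations = cors, alpha = 0.05)
  emph <- g$links[g$links$emphasized, ]
  expect_equal(nrow(emph), 1)
  expect_equal(emph$target, "genus:Klebsiella")
  expect_equal(emph$color_class, "positive")
  # the non-significant genus stays background
  clo <- g$links[g$links$target == "genus:Clostridium", ]
  expect_equal(clo$color_class, "background")
})

test_that("sta-sankey background is the significant taxa, emphasis needs kb support", {
  kb <- phenylalanine_kb()
  cors <- tibble::tibble(
    rank = "genus",
    taxon = c("p__Proteobacteria|c__Gammaproteobacteria|o__Enterobacterales|f__Enterobacteriaceae|g__Klebsiella",
              "p__Firmicutes|c__Bacilli|o__Lactobacillales|f__Streptococcaceae|g__Streptococcus"),
    metabolite = "L-Phenylalanine",
    method = "spearman",
    coefficient = c(0.9, -0.8),
    p_value = c(0.01, 0.02),
    significant = TRUE,
    degenerate = FALSE)
  g <- build_sta_sankey("R00693", cors, kb, alpha = 0.05)
  genera <- g$nodes$label[g$nodes$kind == "genus"]
  expect_setequal(genera, c("Klebsiella", "Streptococcus"))
  kleb <- g$links[g$links$target == "genus:Klebsiella", ]
  strep <- g$links[g$links$target == "genus:Streptococcus", ]
  expect_true(kleb$emphasized)        # Klebsiella carries R00693 in the kb
  expect_equal(kleb$color_class, "positive")
  expect_false(strep$emphasized)      # correlated but biologically unknown
  expect_equal(strep$color_class, "negative")
  # emphasized set equals the brute-force intersection
  sig_taxa <- parse_lineage(cors$taxon)$genus[cors$p_value <= 0.05]
  kb_genera <- kb$organisms$genus[kb$organisms$org_code %in%
    kb$reaction_organisms$org_code[
      kb$reaction_organisms$reaction_id == "R00693"]]
  want_emph <- intersect(sig_taxa, kb_genera)
  got_emph <- sub("^genus:", "",
                  unique(g$links$target[g$links$emphasized]))
  expect_setequal(got_emph, want_emph)
})

test_that("a taxon both biologically listed and statistically significant is emphasized in both variants", {
  kb <- phenylalanine_kb()
  cors <- tibble::tibble(
    rank = "genus",
    taxon = "p__Proteobacteria|c__Gammaproteobacteria|o__Enterobacterales|f__Enterobacteriaceae|g__Klebsiella",
    metabolite = "L-Phenylalanine", method = "spearman",
    coefficient = 0.85, p_value = 0.004, significant = TRUE,
    degenerate = FALSE)
  bio <- build_bio_sankey("R00693", kb, correlations = cors)
  sta <- build_sta_sankey("R00693", cors, kb)
  expect_true(any(bio$links$emphasized &
                    bio$links$target == "genus:Klebsiella"))
  expect_true(any(sta$links$emphasized &
                    sta$links$target == "genus:Klebsiella"))
})

test_that("sta-sankey with no significant taxon degrades to a metabolite-enzyme graph", {
  kb <- phenylalanine_kb()
  cors <- tibble::tibble(rank = "genus", taxon = "p__X|g__Y",
                         metabolite = "L-Phenylalanine",
                         method = "spearman", coefficient = 0.1,
                         p_value = 0.9, significant = FALSE,
                         degenerate = FALSE)
  expect_warning(g <- build_sta_sankey("R00693", cors, kb),
                 "no taxon")
  expect_setequal(unique(g$nodes$kind), c("metabolite", "enzyme"))
})

test_that("summary networks keep host origin metabolite-only and color planted signs", {
  kb <- phenylalanine_kb()
  # a directly constructed significant-pathway table (the single-pathway
  # canned kb cannot be enriched against itself)
  mpea <- tibble::tibble(pathway_id = "map00360", significant = TRUE)
  diff_metab <- tibble::tibble(
    feature_id = c("Benzoate", "Phenyllactate", "N-Acetyl-L-phenylalanine",
                   "3-Hydroxyphenylpropanoate"),
    entry_id = c("MB00003", "MB00004", "MB00002", "MB00005"),
    p_value = 0.001, effect = c(1, -1, 2, 0.5),
    direction = c("up", "down", "up", "up"), significant = TRUE,
    degenerate = FALSE)
  cors <- tibble::tibble(
    rank = "genus",
    taxon = c("p__Proteobacteria|c__Gammaproteobacteria|o__Enterobacterales|f__Enterobacteriaceae|g__Klebsiella",
              "p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Clostridiaceae|g__Clostridium"),
    metabolite = c("Benzoate", "Phenyllactate"), method = "spearman",
    coefficient = c(0.9, -0.85), p_value = c(0.002, 0.003),
    significant = TRUE, degenerate = FALSE)
  net <- build_summary_network("microbiota", mpea, diff_metab, cors, kb,
                               p_threshold = 0.01)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$sign, c("positive", "negative"))
  expect_true(all(net$edges$p_value <= 0.01))
  expect_setequal(net$nodes$shape[net$nodes$kind == "taxon"], "dot")
  expect_setequal(net$nodes$shape[net$nodes$kind == "metabolite"],
                  "diamond")

  host_net <- build_summary_network("host", mpea, diff_metab, cors, kb)
  expect_equal(nrow(host_net$edges), 0)
  expect_true(all(host_net$nodes$kind == "metabolite"))

  empty <- build_summary_network(
    "microbiota", mpea, dplyr::mutate(diff_metab, significant = FALSE),
    cors, kb)
  expect_equal(nrow(empty$nodes), 0)
})

test_that("json export -> import -> export is byte-identical, graphml is valid", {
  kb <- phenylalanine_kb()
  g <- build_bio_sankey("R00693", kb)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_network(g, f1, "json")
  g2 <- import_network(f1)
  export_network(g2, f2, "json")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$links, g$links)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, gml, "graphml")
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), nrow(g$nodes))
  expect_equal(igraph::gsize(ig), nrow(g$links))
  # link-width multiset preserved across formats
  expect_equal(sort(igraph::E(ig)$width), sort(g$links$width))

  html <- withr::local_tempfile(fileext = ".html")
  export_network(g, html, "html")
  expect_match(readLines(html, n = 1), "<!DOCTYPE html>")
  expect_error(export_network(g, f1, "xlsx"))
})

test_that("summary networks survive the json round trip", {
  kb <- phenylalanine_kb()
  mpea <- tibble::tibble(pathway_id = "map00360", significant = TRUE)
  diff_metab <- tibble::tibble(
    feature_id = "Benzoate", entry_id = "MB00003", p_value = 0.001,
    effect = 1, direction = "up", significant = TRUE, degenerate = FALSE)
  net <- build_summary_network("host", mpea, diff_metab, NULL, kb)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  export_network(net, f1, "json")
  export_network(import_network(f1), f2, "json")
  expect_identical(readLines(f1), readLines(f2))
})
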