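# Taxon-metabolite correlation, rank aggregation and the approximate MIC.

lineages <- c(
  "p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Clostridiaceae|g__Clostridium|s__Clostridium a",
  "p__Firmicutes|c__Clostridia|o__Eubacteriales|f__Clostridiaceae|g__Clostridium|s__Clostridium b",
  "p__Firmicutes|c__Bacilli|o__Bacillales|f__Bacillaceae|g__Bacillus|s__Bacillus a",
  "p__Proteobacteria|c__Gammaproteobacteria|o__Enterobacterales|f__Enterobacteriaceae|g__Escherichia|s__Escherichia a")

taxa_tbl <- function(mat) {
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(taxon = lineages[seq_len(nrow(mat))]),
                   tibble::as_tibble(mat))
}

met_tbl <- function(mat, ids = sprintf("m%d", seq_len(nrow(mat)))) {
  colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  dplyr::bind_cols(tibble::tibble(name = ids), tibble::as_tibble(mat))
}

test_that("lineage parsing handles prefixes, separators and gaps", {
  lin <- parse_lineage(c("p__A|c__B|o__C|f__D|g__E|s__F",
                         "p__A;c__B",
                         "p__A|g__E"))
  expect_equal(lin$species, c("F", "unclassified", "unclassified"))
  expect_equal(lin$genus, c("E", "unclassified", "E"))
  expect_equal(lin$class[3], "unclassified")
})

test_that("rank aggregation sums child abundances", {
  mat <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  gen <- aggregate_taxa(taxa_tbl(mat), "genus")
  clo <- as.numeric(gen[grep("Clostridium", gen$taxon), -1])
  expect_equal(clo, c(4, 6))
  phy <- aggregate_taxa(taxa_tbl(mat), "phylum")
  expect_equal(sort(as.numeric(as.matrix(phy[, -1]))),
               sort(c(1 + 3 + 5, 2 + 4 + 6, 7, 8)))
})

test_that("monotone and anti-linear relationships give the textbook coefficients", {
  m <- met_tbl(matrix(c(10, 100, 1000, 10000), nrow = 1))
  t1 <- taxa_tbl(matrix(c(1, 2, 3, 4), nrow = 1))
  sp <- correlate(m, t1, "spearman", rank = "species")
  expect_equal(sp$coefficient, 1)

  m2 <- met_tbl(matrix(c(3, 2, 1), nrow = 1))
  t2 <- taxa_tbl(matrix(c(1, 2, 3), nrow = 1))
  pe <- correlate(m2, t2, "pearson", rank = "species")
  expect_equal(pe$coefficient, -1)
})

test_that("spearman equals rank-then-pearson from an independent rank oracle", {
  withr::with_seed(17, {
    for (i in 1:5) {
      x <- rnorm(5)
      y <- rnorm(5)
      got <- correlate(met_tbl(matrix(exp(y), nrow = 1)),
                       taxa_tbl(matrix(exp(x), nrow = 1)),
                       "spearman", rank = "species")$coefficient
      expect_equal(got, cor(rank(x), rank(y)), tolerance = 1e-12)
    }
  })
})

test_that("spearman is invariant under strictly increasing transforms", {
  withr::with_seed(23, {
    x <- rlnorm(12)
    y <- rlnorm(12)
  })
  base <- correlate(met_tbl(matrix(y, nrow = 1)),
                    taxa_tbl(matrix(x, nrow = 1)),
                    "spearman", rank = "species")$coefficient
  for (f in list(exp, \(v) rank(v), \(v) 3 * v + 7)) {
    tr <- correlate(met_tbl(matrix(f(y), nrow = 1)),
                    taxa_tbl(matrix(x, nrow = 1)),
                    "spearman", rank = "species")$coefficient
    expect_equal(tr, base, tolerance = 1e-12)
  }
})

test_that("constant vectors are degenerate, not errors", {
  res <- correlate(met_tbl(matrix(c(1, 2, 3, 4), nrow = 1)),
                   taxa_tbl(matrix(c(5, 5, 5, 5), nrow = 1)),
                   "pearson", rank = "species")
  expect_true(res$degenerate)
  expect_equal(res$coefficient, 0)
  expect_equal(res$p_value, 1)
})

test_that("sample alignment intersects ids and refuses tiny overlap", {
  m <- met_tbl(matrix(1:4, nrow = 1))
  t_small <- taxa_tbl(matrix(1:2, nrow = 1))  # S01..S02 only
  expect_error(correlate(m, t_small, "pearson", rank = "species"),
               "shared samples")
})

test_that("significance filtering equals a brute-force filter", {
  withr::with_seed(6, {
    m <- met_tbl(matrix(rlnorm(3 * 10), nrow = 3))
    t3 <- taxa_tbl(matrix(rlnorm(3 * 10), nrow = 3))
  })
  res <- correlate(m, t3, "spearman", rank = "species")
  kept <- filter_significant(res, alpha = 0.4)
  expect_setequal(
    paste(kept$taxon, kept$metabolite),
    paste(res$taxon, res$metabolite)[res$p_value <= 0.4 & !res$degenerate])
  expect_equal(nrow(filter_significant(res, alpha = 0)), 0)
  expect_equal(nrow(filter_significant(res, alpha = 1)),
               sum(!res$degenerate))
})

test_that("mic saturates on noiseless functions, stays low under independence, is symmetric", {
  withr::with_seed(41, {
    x <- sample(seq_len(100))
  })
  expect_gte(mic_score(x, x), 0.99)
  expect_gte(mic_score(x, (x - 50)^2), 0.6)   # non-monotone but functional
  withr::with_seed(42, {
    a <- rnorm(100)
    b <- rnorm(100)
  })
  expect_lt(mic_score(a, b), 0.3)
  withr::with_seed(43, {
    u <- rnorm(60)
    v <- rnorm(60)
  })
  expect_equal(mic_score(u, v), mic_score(v, u))
  expect_error(mic_score(1:5, 1:5), "at least 8")
})

test_that("mic correlation pairs carry a permutation p-value", {
  withr::with_seed(51, {
    x <- rnorm(30)
    m <- met_tbl(matrix(exp(x + rnorm(30, sd = 0.2)), nrow = 1))
    t1 <- taxa_tbl(matrix(exp(x), nrow = 1))
  })
  res <- correlate(m, t1, "mic", rank = "species", n_perm = 99, seed = 2)
  expect_true(res$coefficient > 0.3)
  expect_lt(res$p_value, 0.05)
  res2 <- correlate(m, t1, "mic", rank = "species", n_perm = 99, seed = 2)
  expect_identical(res$p_value, res2$p_value)
})
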