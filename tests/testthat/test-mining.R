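# mention mining: tokenization, matching, indexing, frequency filter,
# chromosome distribution

test_that("normalize_text follows the stated tokenization rules", {
  expect_identical(normalize_text(""), character())
  expect_identical(normalize_text("the the HNF4A gene gene",
                                  stop_phrases = c("the", "gene")),
                   "HNF4A")
  expect_identical(normalize_text("HLA-DRB1, and TCF7L2.",
                                  stop_phrases = "and"),
                   c("HLA-DRB1", "TCF7L2"))
  # stop removal is case-insensitive; case is preserved on survivors
  expect_identical(normalize_text("The INS Gene", stop_phrases = c("the", "gene")),
                   "INS")
  # consecutive duplicates collapse, non-consecutive repeats survive
  expect_identical(normalize_text("INS INS TCF7L2 INS", stop_phrases = character()),
                   c("INS", "TCF7L2", "INS"))
})

test_that("match_genes is exact, case-sensitive, alias- and blacklist-aware", {
  catalog <- tiny_catalog()
  expect_identical(match_genes("HNF4A", catalog), "HNF4A")
  expect_identical(match_genes("hnf4a", catalog), character())
  expect_identical(match_genes("SET", catalog, blacklist = "SET"), character())
  expect_identical(match_genes("SET", catalog, blacklist = character()), "SET")
  # alias resolves to canonical symbol; blacklist applies to the matched string
  expect_identical(match_genes("NR2A1", catalog), "HNF4A")
  expect_identical(match_genes("NR2A1", catalog, blacklist = "NR2A1"), character())
  expect_error(match_genes("X", gene_catalog(
    data.frame(symbol = character(), chromosome = character(),
               start = numeric()))), "non-empty")
})

test_that("build_index counts an article once per gene and matches planted truth", {
  catalog <- generate_catalog(40, 8, seed = 2)
  expect_equal(build_index(data.frame(article_id = character(),
                                      text = character()),
                           catalog)$n_articles_scanned, 0)

  plan <- c(G0005 = 12L, G0010 = 7L, G0020 = 1L)
  corp <- generate_corpus(catalog, 60, plan, seed = 5)
  idx <- build_index(corp, catalog)
  expect_equal(idx$n_articles_scanned, 60)
  expect_identical(idx$per_gene[names(plan)[1:2]], corp$truth[names(plan)[1:2]])

  # within-article repeats count once
  rep_corpus <- data.frame(article_id = "A1",
                           text = "G0005 noise G0005 noise G0005 G0005 G0005")
  idx_rep <- build_index(rep_corpus, catalog)
  expect_identical(idx_rep$per_gene$G0005, "A1")

  expect_error(build_index(data.frame(article_id = "A1", text = NA_character_),
                           catalog), "unreadable")
})

test_that("build_index equals a brute-force regex scan and recovers truth perfectly", {
  catalog <- generate_catalog(30, 6, seed = 3)
  for (s in 1:5) {
    plan <- setNames(sample(0:15, 8), catalog$genes$symbol[1:8])
    corp <- generate_corpus(catalog, 50, plan, seed = s)
    idx <- build_index(corp, catalog, stop_phrases = character(),
                       blacklist = character())
    expect_identical(idx$per_gene, oracle_scan_corpus(corp, catalog))
    # precision = recall = 1 against planted truth (no ambiguity decoys)
    truth <- corp$truth[lengths(corp$truth) > 0]
    expect_identical(idx$per_gene, truth[order(names(truth))])
  }
})

test_that("filter_frequent applies a strict threshold with deterministic ordering", {
  idx <- structure(list(per_gene = list(A = sprintf("A%02d", 1:51),
                                        B = sprintf("A%02d", 1:50),
                                        C = sprintf("A%02d", 1:7)),
                        n_articles_scanned = 60L),
                   class = "mention_index")
  ft <- filter_frequent(idx, 50)
  expect_equal(ft$symbol, "A")
  expect_equal(ft$article_count, 51)
  expect_equal(attr(ft, "threshold_used"), 50L)

  empty <- structure(list(per_gene = list(), n_articles_scanned = 0L),
                     class = "mention_index")
  expect_equal(nrow(filter_frequent(empty, 50)), 0)

  # ties break lexicographically; sorting is by descending count
  idx2 <- structure(list(per_gene = list(Z = c("a", "b"), A = c("a", "b"),
                                         M = c("a", "b", "c")),
                         n_articles_scanned = 3L),
                    class = "mention_index")
  expect_equal(filter_frequent(idx2, 0)$symbol, c("M", "A", "Z"))

  # monotonicity: raising the threshold never adds genes
  catalog <- generate_catalog(30, 6, seed = 3)
  plan <- setNames(sample(0:30, 10), catalog$genes$symbol[1:10])
  idx3 <- build_index(generate_corpus(catalog, 40, plan, seed = 1), catalog)
  prev <- filter_frequent(idx3, 0)$symbol
  for (thr in c(2, 5, 10, 20)) {
    cur <- filter_frequent(idx3, thr)$symbol
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("planted frequency boundary: 51 survives a >50 filter, 50 does not", {
  catalog <- generate_catalog(10, 3, seed = 1)
  corp <- generate_corpus(catalog, 100, c(G0001 = 51L, G0002 = 50L), seed = 4)
  ft <- filter_frequent(build_index(corp, catalog), 50)
  expect_identical(ft$symbol, "G0001")
})

test_that("chromosome_distribution conserves counts and includes zeros", {
  catalog <- grid_catalog(10, per_chrom = 2)  # 5 chromosomes x 2 genes
  ft <- structure(data.frame(symbol = catalog$genes$symbol,
                             article_count = 10L),
                  class = c("frequency_table", "data.frame"))
  dist <- chromosome_distribution(ft, catalog)
  expect_true(all(dist == 2))
  expect_equal(sum(dist), nrow(ft))

  one <- ft[ft$symbol == "G001", , drop = FALSE]
  d1 <- chromosome_distribution(one, catalog)
  expect_equal(unname(d1["chr1"]), 1)
  expect_equal(sum(d1), 1)
  expect_equal(sum(d1 == 0), 4)

  bad <- data.frame(symbol = c("G001", "NOPE"), article_count = 5L)
  expect_error(chromosome_distribution(bad, catalog), "NOPE")
})
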