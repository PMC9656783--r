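# generators: determinism, invariants, truth consistency

test_that("generate_catalog respects size, bounds and determinism", {
  one <- generate_catalog(1, 1, seed = 7)
  expect_equal(nrow(one$genes), 1)
  expect_gte(one$genes$start, 0)

  a <- generate_catalog(200, 22, seed = 1)
  b <- generate_catalog(200, 22, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_catalog(200, 22, seed = 2)))

  # exhaustive invariant scan
  expect_equal(nrow(a$genes), 200)
  expect_false(anyDuplicated(a$genes$symbol) > 0)
  expect_true(all(a$genes$chromosome %in% paste0("chr", 1:22)))
  expect_true(all(a$genes$start >= 0))
  expect_true(length(intersect(names(a$aliases), a$genes$symbol)) == 0)

  # proximity plumbing: a close pair and a far pair both exist
  same <- outer(a$genes$chromosome, a$genes$chromosome, "==")
  d <- abs(outer(a$genes$start, a$genes$start, "-"))
  offdiag <- upper.tri(d)
  expect_true(any(same[offdiag] & d[offdiag] < 1e6))
  expect_true(any(same[offdiag] & d[offdiag] >= 1e6))

  expect_error(generate_catalog(0, 5), "n_genes")
  expect_error(generate_catalog(10, 0), "n_chromosomes")
})

test_that("generate_corpus plants exactly the planned mention counts", {
  catalog <- generate_catalog(30, 5, seed = 1)
  plan <- c(G0001 = 51L, G0002 = 50L, G0003 = 0L)
  corp <- generate_corpus(catalog, 100, plan, seed = 3)

  expect_length(corp$truth$G0001, 51)
  expect_length(corp$truth$G0002, 50)
  expect_length(corp$truth$G0003, 0)
  expect_false(any(grepl("G0003", corp$articles$text, fixed = TRUE)))

  # recount the truth by scanning the generated texts with exact search
  rescan <- oracle_scan_corpus(corp, catalog)
  expect_identical(rescan[["G0001"]], corp$truth$G0001)
  expect_identical(rescan[["G0002"]], corp$truth$G0002)

  expect_identical(corp, generate_corpus(catalog, 100, plan, seed = 3))
  expect_error(generate_corpus(catalog, 10, c(G0001 = 11L)), "exceed")
  expect_error(generate_corpus(catalog, 10, c(NOPE = 2L)), "absent")
})

test_that("ambiguity decoys are recorded separately from mention truth", {
  catalog <- gene_catalog(
    data.frame(symbol = c("SET", "G1"), chromosome = "chr1", start = c(0, 5e6)))
  corp <- generate_corpus(catalog, 40, c(G1 = 5L),
                          ambiguous_tokens = "SET", seed = 2)
  expect_true(length(corp$ambiguous$SET) >= 1)
  expect_null(corp$truth$SET)
  expect_true(any(grepl("\\bSET\\b", corp$articles$text)))
})

test_that("generate_expression plants recoverable effect sizes and correlation blocks", {
  catalog <- generate_catalog(100, 10, seed = 4)
  design <- data.frame(dataset_id = c("D1", "D2"), platform_id = c("PA", "PB"),
                       n_case = 20, n_control = 20)

  # null model: no truth, group means differ only by noise
  null <- generate_expression(catalog, design, de_fraction = 0, seed = 5)
  expect_length(attr(null, "truth")$deg, 0)
  gm <- genetriage:::collapse_markers(null$D1$matrix, null$D1$marker_to_gene)
  diffs <- rowMeans(gm[, null$D1$labels == "case"]) -
    rowMeans(gm[, null$D1$labels == "control"])
  expect_lt(max(abs(diffs)), 1.5)  # ~ noise_sd / sqrt(10) scale, never effect-sized

  # planted effect: recompute Hedges' g from the matrix, must be near 3
  dss <- generate_expression(catalog, design, de_fraction = 0.1, effect_size = 3,
                             noise_sd = 1, corr_block_spec = list(c(5, 0.9)),
                             seed = 6)
  truth <- attr(dss, "truth")
  gmat <- genetriage:::collapse_markers(dss$D1$matrix, dss$D1$marker_to_gene)
  is_case <- dss$D1$labels == "case"
  gs <- vapply(names(truth$deg), function(g)
    hedges_g(gmat[g, is_case], gmat[g, !is_case])$g * sign(truth$deg[[g]]),
    numeric(1))
  expect_lt(abs(gs[1] - 3), 1.0)         # a planted gene lands in the 3 +/- 1 band
  expect_lt(abs(mean(gs) - 3), 0.5)      # and the planted cohort is centred on 3
  expect_true(all(abs(gs - 3) < 1.5))

  # correlation block: mean pairwise r within block well above background
  blk <- truth$corr_blocks[[1]]
  R <- cor(t(gmat[blk, ]))
  expect_gt(mean(R[upper.tri(R)]), 0.5)

  expect_identical(
    generate_expression(catalog, design, de_fraction = 0.1, effect_size = 3,
                        noise_sd = 1, corr_block_spec = list(c(5, 0.9)), seed = 6),
    dss)
  expect_error(generate_expression(catalog, design,
                                   corr_block_spec = list(c(200, 0.5))),
               "block size")
  expect_error(generate_expression(
    catalog, data.frame(dataset_id = "D", platform_id = "P",
                        n_case = 1, n_control = 5)), ">= 2")
})

test_that("count-scale generation yields valid non-negative matrices", {
  catalog <- generate_catalog(50, 5, seed = 1)
  design <- data.frame(dataset_id = "D1", platform_id = "P", n_case = 4, n_control = 4)
  dss <- generate_expression(catalog, design, de_fraction = 0.1, effect_size = 2,
                             scale = "counts", seed = 3)
  expect_true(all(dss$D1$matrix >= 0))
  expect_true(all(dss$D1$matrix == round(dss$D1$matrix)))
})

test_that("generate_annotations respects sizes, planting and determinism", {
  catalog <- generate_catalog(60, 6, seed = 2)
  n <- nrow(catalog$genes)

  # saturation: a single term the size of the whole background
  sat <- generate_annotations(catalog, 1, c(n, n), seed = 1)
  expect_setequal(sat$terms$members[[1]], sat$background)

  ann <- generate_annotations(catalog, 20, c(5, 30),
                              enriched_term_spec = list(
                                term_id = "T_X", genes = catalog$genes$symbol[1:8],
                                size = 20),
                              seed = 9)
  expect_true(all(lengths(ann$terms$members[ann$terms$term_id != "T_X"]) >= 5))
  expect_true(all(lengths(ann$terms$members[ann$terms$term_id != "T_X"]) <= 30))
  planted <- ann$terms$members[[which(ann$terms$term_id == "T_X")]]
  expect_true(all(catalog$genes$symbol[1:8] %in% planted))
  expect_identical(ann, generate_annotations(
    catalog, 20, c(5, 30),
    enriched_term_spec = list(term_id = "T_X",
                              genes = catalog$genes$symbol[1:8], size = 20),
    seed = 9))
  expect_error(generate_annotations(catalog, 5, c(10, 1000)), "catalog size")
})

test_that("writers and readers round-trip every artifact", {
  catalog <- generate_catalog(25, 4, seed = 8)
  dir <- withr::local_tempdir()

  write_catalog(catalog, file.path(dir, "cat.bed"))
  back <- read_catalog(file.path(dir, "cat.bed"))
  expect_equal(back$genes, catalog$genes)
  expect_equal(back$aliases, catalog$aliases)

  corp <- generate_corpus(catalog, 20, c(G0001 = 5L), seed = 1)
  write_corpus(corp, file.path(dir, "corpus.tsv"))
  expect_equal(read_corpus(file.path(dir, "corpus.tsv")), corp$articles)

  design <- data.frame(dataset_id = "D1", platform_id = "P", n_case = 3, n_control = 3)
  ds <- generate_expression(catalog, design, seed = 2)$D1
  write_expression(ds, file.path(dir, "expr.tsv"))
  back_ds <- read_expression(file.path(dir, "expr.tsv"), "D1", "P")
  expect_equal(back_ds$matrix, ds$matrix, tolerance = 1e-10)
  expect_equal(back_ds$labels, ds$labels)
  expect_equal(back_ds$marker_to_gene, ds$marker_to_gene)

  ann <- generate_annotations(catalog, 6, c(3, 10), seed = 3)
  write_gmt(ann, file.path(dir, "sets.gmt"))
  back_ann <- read_gmt(file.path(dir, "sets.gmt"), background = ann$background)
  expect_equal(back_ann$terms$term_id, ann$terms$term_id)
  expect_equal(back_ann$terms$category, ann$terms$category)
  expect_equal(lapply(back_ann$terms$members, sort),
               lapply(ann$terms$members, sort))
})

test_that("MEDLINE-like corpora are parsed", {
  path <- withr::local_tempfile()
  writeLines(c("PMID- 100", "TI  - irrelevant", "AB  - HNF4A is mentioned here",
               "      and continued on this line.", "",
               "PMID- 101", "AB  - nothing of note."), path)
  df <- read_medline(path)
  expect_equal(df$article_id, c("100", "101"))
  expect_match(df$text[1], "continued")
})
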