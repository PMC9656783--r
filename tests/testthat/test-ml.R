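# biomarker ranking: feature assembly, splits, models, explanations, tallies

test_that("assemble_features combines group datasets on shared markers", {
  catalog <- generate_catalog(40, 5, seed = 1)
  design <- data.frame(dataset_id = c("D1", "D2", "D3"),
                       platform_id = c("PA", "PA", "PB"),
                       n_case = c(5, 6, 5), n_control = c(5, 6, 5))
  dss <- generate_expression(catalog, design, de_fraction = 0.1, seed = 2)
  sel <- catalog$genes$symbol
  ft <- assemble_features(dss, sel, list(A = c("D1", "D2"), B = "D3"))

  expect_equal(nrow(ft$A$X), 22)   # sample count is the sum over the group
  expect_equal(nrow(ft$B$X), 10)
  # same-platform datasets share markers, so the intersection is complete
  expect_setequal(colnames(ft$A$X), names(dss$D1$marker_to_gene))

  # single dataset, no normalization: table = transposed restriction
  ft_raw <- assemble_features(dss["D3"], sel, list(B = "D3"),
                              normalize = "none")
  expect_equal(ft_raw$B$X, t(dss$D3$matrix))

  # markers absent from one group dataset are dropped with a message
  d2 <- dss$D2
  keep <- rownames(d2$matrix)[-1]
  d2trim <- expression_dataset("D2", "PA", d2$matrix[keep, ],
                               d2$marker_to_gene[keep], d2$labels)
  expect_message(
    ft2 <- assemble_features(list(dss$D1, d2trim), sel, list(A = c("D1", "D2"))),
    "dropped 1 marker")
  expect_false(rownames(dss$D2$matrix)[1] %in% colnames(ft2$A$X))
})

test_that("split_70_30 is stratified, disjoint and deterministic", {
  ft <- small_feature_table(n_per_class = 5)
  sp <- split_70_30(ft, seed = 3)
  expect_equal(nrow(sp$train$X), 7)  # ceiling(0.7 * 10)
  expect_equal(nrow(sp$test$X), 3)
  expect_true(all(c("case", "control") %in% sp$train$y))
  expect_true(all(c("case", "control") %in% sp$test$y))
  sp2 <- split_70_30(ft, seed = 3)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_70_30(ft, seed = 4)))

  # class proportions within one sample of the stratified target, always
  ft2 <- small_feature_table(n_per_class = 9)
  for (s in 1:50) {
    tr <- split_70_30(ft2, seed = s)$train
    expect_lte(abs(sum(tr$y == "case") - 0.7 * 9), 1)
  }

  single <- feature_table("g", matrix(rnorm(6), 3,
                                      dimnames = list(NULL, c("a", "b"))),
                          c("case", "control", "control"),
                          c(a = "GA", b = "GB"))
  expect_error(split_70_30(single), "stratification")
})

test_that("a planted separable marker gives perfect accuracy and top rank", {
  ft <- small_feature_table(n_per_class = 20, n_markers = 10,
                            sep_marker = "M03", sep = 6, seed = 7)
  sp <- split_70_30(ft, seed = 1)
  for (alg in c("decision_tree", "random_forest", "extra_trees")) {
    r <- train_and_score(sp$train, sp$test, alg, n_trees = 100, seed = 2)
    expect_equal(r$accuracy, 1.0)
    expect_equal(r$importances$marker[1], "M03")
    expect_true(r$ci_low <= r$accuracy && r$accuracy <= r$ci_high)
    expect_equal(sum(r$importances$importance), 100)
    expect_true(all(r$importances$importance >= 0))
    expect_equal(r$importances$gene[1], "GENE03")
  }
  # determinism
  r1 <- train_and_score(sp$train, sp$test, "random_forest", n_trees = 50, seed = 9)
  r2 <- train_and_score(sp$train, sp$test, "random_forest", n_trees = 50, seed = 9)
  expect_equal(r1$accuracy, r2$accuracy)
  expect_equal(r1$importances, r2$importances)
  expect_error(train_and_score(sp$train, sp$test, "boosting"), "arg")
})

test_that("permuted labels give chance-level accuracy covered by the Wilson CI", {
  covered <- 0L
  for (s in 1:12) {
    ft <- small_feature_table(n_per_class = 15, n_markers = 8, seed = s)
    ft$y <- withr::with_seed(100 + s, sample(ft$y))   # break any structure
    sp <- split_70_30(ft, seed = s)
    r <- train_and_score(sp$train, sp$test, "random_forest",
                         n_trees = 100, seed = s)
    if (r$ci_low <= 0.5 && 0.5 <= r$ci_high) covered <- covered + 1L
  }
  expect_gte(covered / 12, 0.75)
})

test_that("Wilson interval contains the estimate and narrows with test size", {
  ft_small <- small_feature_table(n_per_class = 8, sep_marker = "M01", seed = 1)
  ft_big <- small_feature_table(n_per_class = 60, sep_marker = "M01", seed = 1)
  r_small <- train_and_score(split_70_30(ft_small, 1)$train,
                             split_70_30(ft_small, 1)$test,
                             "decision_tree", seed = 1)
  r_big <- train_and_score(split_70_30(ft_big, 1)$train,
                           split_70_30(ft_big, 1)$test,
                           "decision_tree", seed = 1)
  expect_lt(r_big$ci_high - r_big$ci_low, r_small$ci_high - r_small$ci_low)
})

test_that("local explanations recover a linear black box and vanish for a constant one", {
  set.seed(3)
  d <- 6
  B <- matrix(rnorm(150 * d), 150, d, dimnames = list(NULL, paste0("f", 1:d)))
  a <- c(2, -1.5, 0.8, 0, 1.2, -0.4)
  lin <- function(X) as.numeric(X %*% a)
  ex <- local_explanations(lin, B[1, ], B, n_perturbations = 3000,
                           n_features_out = d, seed = 4)
  w <- setNames(ex$weight, ex$marker)[colnames(B)]
  expect_gt(cor(w, a), 0.95)
  expect_equal(unname(w), a, tolerance = 0.01)

  const <- function(X) rep(0.7, nrow(X))
  ex0 <- local_explanations(const, B[1, ], B, n_perturbations = 5000,
                            n_features_out = d, seed = 5)
  expect_true(all(abs(ex0$weight) < 0.01))

  # determinism and location-shift invariance of the background
  ex_a <- local_explanations(lin, B[1, ], B, n_perturbations = 500, seed = 6)
  ex_b <- local_explanations(lin, B[1, ], B, n_perturbations = 500, seed = 6)
  expect_identical(ex_a, ex_b)
  B_shift <- B; B_shift[, 2] <- B_shift[, 2] + 100
  ex_c <- local_explanations(lin, B[1, ], B_shift, n_perturbations = 500, seed = 6)
  expect_equal(ex_a, ex_c)

  # zero-variance background features are excluded with a message
  B0 <- B; B0[, 4] <- 1
  expect_message(ex_z <- local_explanations(lin, B[1, ], B0,
                                            n_perturbations = 500, seed = 7),
                 "zero-variance")
  expect_false("f4" %in% ex_z$marker)
})

test_that("tally_recurrence counts markers and aggregates genes", {
  ft <- small_feature_table(n_per_class = 12, n_markers = 6,
                            sep_marker = "M02", sep = 6, seed = 2)
  sp <- split_70_30(ft, seed = 1)
  reports <- lapply(1:4, function(s)
    train_and_score(sp$train, sp$test, "random_forest", n_trees = 60, seed = s))
  tal <- tally_recurrence(reports, top_k = 3)
  expect_equal(tal$markers$marker[1], "M02")
  expect_equal(tal$markers$count[1], 4)        # dominant marker in all 4 runs
  expect_equal(tal$genes$gene[1], "GENE02")
  expect_true(all(tal$markers$count <= 4))
  # gene count >= max of its markers' counts
  for (g in tal$genes$gene) {
    expect_gte(tal$genes$count[tal$genes$gene == g],
               max(tal$markers$count[tal$markers$gene == g]))
  }
  one <- tally_recurrence(reports[1], top_k = 100)
  expect_true(all(one$markers$count == 1))
  expect_error(tally_recurrence(list()), "non-empty")
})
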