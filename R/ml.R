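# Tree-ensemble biomarker ranking: feature assembly per platform group,
# stratified 70/30 split, decision tree / random forest / extra-trees
# scoring with Wilson confidence intervals, impurity importances, local
# surrogate (perturbation-based) explanations, and recurrence tallies.

#' Feature-table container
#'
#' @param group_id platform-group label.
#' @param X samples x markers numeric matrix (no missing values).
#' @param y per-sample class, `"case"` / `"control"`, both present.
#' @param marker_to_gene named character vector, marker -> gene.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(group_id, X, y, marker_to_gene) {
  stopifnot(is.matrix(X), is.numeric(X))
  if (anyNA(X)) stop_arg("feature table contains missing values")
  y <- as.character(y)
  if (length(y) != nrow(X)) stop_arg("labels must match sample rows")
  if (length(unique(y)) < 2)
    stop_arg("configuration error: both classes must be present in group %s", group_id)
  if (anyDuplicated(colnames(X))) stop_arg("marker codes must be unique")
  structure(list(group_id = group_id, X = X, y = y,
                 marker_codes = colnames(X),
                 marker_to_gene = marker_to_gene[colnames(X)]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> group %s: %d samples x %d markers (%d case / %d control)\n",
              x$group_id, nrow(x$X), ncol(x$X),
              sum(x$y == "case"), sum(x$y == "control")))
  invisible(x)
}

#' Assemble per-platform-group feature tables
#'
#' Datasets within a group (same chip platform) are column-combined: the
#' sample count is the sum, the marker set is the intersection of the
#' group's datasets restricted to markers mapping to `selected_genes`
#' (markers missing from any group dataset are dropped with a message).
#' Each dataset is TMM-normalized sample-wise (via [tmm_factors()]) before
#' combination; use `normalize = "none"` for matrices where a library-size
#' notion does not apply.
#'
#' @param datasets named list of [expression_dataset()] objects.
#' @param selected_genes gene symbols whose markers become features
#'   (typically the union of literature-frequent genes and meta-analysis
#'   DEGs).
#' @param platform_groups named list: group id -> character vector of
#'   dataset ids.
#' @param normalize `"tmm"` (default) or `"none"`.
#' @return list of [feature_table()] objects, one per group.
#' @export
assemble_features <- function(datasets, selected_genes, platform_groups,
                              normalize = c("tmm", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(length(platform_groups) >= 1, !is.null(names(platform_groups)))
  ids <- vapply(datasets, `[[`, character(1), "dataset_id")
  names(datasets) <- ids
  lapply_names <- names(platform_groups)
  out <- lapply(lapply_names, function(grp) {
    members <- platform_groups[[grp]]
    missing <- setdiff(members, ids)
    if (length(missing))
      stop_arg("group %s references unknown dataset(s): %s", grp,
               paste(missing, collapse = ", "))
    dss <- datasets[members]
    sel_markers <- lapply(dss, function(ds)
      names(ds$marker_to_gene)[ds$marker_to_gene %in% selected_genes])
    shared <- Reduce(intersect, sel_markers)
    dropped <- setdiff(unique(unlist(sel_markers)), shared)
    if (length(dropped))
      message(sprintf("group %s: dropped %d marker(s) absent from some dataset",
                      grp, length(dropped)))
    if (!length(shared))
      stop_arg("group %s: no selected marker is present in all its datasets", grp)
    blocks <- lapply(dss, function(ds) {
      mat <- ds$matrix
      if (normalize == "tmm") {
        if (any(mat < 0))
          stop_arg("TMM normalization needs non-negative values (dataset %s); use normalize = 'none'",
                   ds$dataset_id)
        mat <- normalize_tmm(mat)
      }
      t(mat[shared, , drop = FALSE])
    })
    X <- do.call(rbind, blocks)
    y <- unlist(lapply(dss, `[[`, "labels"), use.names = FALSE)
    feature_table(grp, X, y, dss[[1]]$marker_to_gene)
  })
  stats::setNames(out, lapply_names)
}

#' Stratified 70/30 train/test split
#'
#' The training set holds `ceiling(train_frac * n)` samples overall,
#' allocated per class by largest-remainder rounding of the stratified
#' target, so class proportions in the training set are always within one
#' sample of the target. Deterministic given the seed.
#'
#' @param table a [feature_table()] with >= 2 samples per class.
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.7).
#' @return list with `train` and `test` [feature_table()]s (disjoint).
#' @export
split_70_30 <- function(table, seed = 1L, train_frac = 0.7) {
  stopifnot(inherits(table, "feature_table"))
  train_frac <- check_prob(train_frac, "train_frac")
  cls <- table(table$y)
  if (any(cls < 2)) stop_arg("stratification error: every class needs >= 2 samples")
  n <- nrow(table$X)
  n_train <- ceiling(train_frac * n)
  base <- floor(train_frac * cls)
  frac <- train_frac * cls - base
  short <- n_train - sum(base)
  extra <- names(sort(frac, decreasing = TRUE))[seq_len(short)]
  target <- base + as.integer(names(cls) %in% extra)
  take <- with_seed(seed, {
    unlist(lapply(names(cls), function(k) {
      idx <- which(table$y == k)
      sample(idx, target[[k]])
    }), use.names = FALSE)
  })
  take <- sort(take)
  sub <- function(i) feature_table(table$group_id,
                                   table$X[i, , drop = FALSE], table$y[i],
                                   table$marker_to_gene)
  list(train = sub(take), test = sub(setdiff(seq_len(n), take)))
}

# internal: safe column names for formula interfaces, with a back-map
safe_frame <- function(X) {
  safe <- sprintf("F%05d", seq_len(ncol(X)))
  df <- as.data.frame(X)
  names(df) <- safe
  attr(df, "marker_of") <- stats::setNames(colnames(X), safe)
  df
}

#' Train a tree model and score it on held-out data
#'
#' Algorithms mirror the usual tree-ensemble toolbox: `"decision_tree"`
#' (rpart), `"random_forest"` (randomForest, mean decrease in Gini), and
#' `"extra_trees"` (ranger with the extra-trees split rule, fitted as a
#' regressor on a 0/1 class encoding — the conventional reading of an
#' "extra-tree regressor" applied to a binary label — with impurity
#' importances). Accuracy is the fraction correct on the test set, with a
#' 95% Wilson score interval. Importances are reported both raw and
#' rescaled to sum to 100.
#'
#' @param train,test [feature_table()]s from [split_70_30()].
#' @param algorithm one of `"decision_tree"`, `"random_forest"`,
#'   `"extra_trees"`.
#' @param n_trees ensemble size (ignored by the single tree).
#' @param seed integer seed for all stochastic steps.
#' @return Object of class `model_report`: list with `algorithm`,
#'   `group_id`, `accuracy`, `ci_low`, `ci_high`, `n_test`, `importances`
#'   (data.frame `marker`, `importance` [sums to 100], `raw`, `gene`,
#'   sorted descending), `seed`, and `predict_fun` (maps a feature matrix to
#'   case scores in `[0, 1]`, used by [local_explanations()]).
#' @export
train_and_score <- function(train, test,
                            algorithm = c("decision_tree", "random_forest",
                                          "extra_trees"),
                            n_trees = 500L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (nrow(test$X) == 0) stop_arg("test set must be non-empty")
  if (!identical(colnames(train$X), colnames(test$X)))
    stop_arg("train and test feature columns differ")
  n_trees <- check_count(n_trees, "n_trees")
  dtr <- safe_frame(train$X)
  marker_of <- attr(dtr, "marker_of")
  ytr <- factor(train$y, levels = c("control", "case"))

  fit_env <- with_seed(seed, {
    if (algorithm == "decision_tree") {
      dtr$..y <- ytr
      fit <- rpart::rpart(..y ~ ., data = dtr, method = "class")
      raw <- fit$variable.importance
      pred_fun <- function(Xs) stats::predict(fit, Xs, type = "prob")[, "case"]
    } else if (algorithm == "random_forest") {
      fit <- randomForest::randomForest(x = dtr, y = ytr, ntree = n_trees,
                                        importance = FALSE)
      raw <- stats::setNames(randomForest::importance(fit, type = 2)[, 1],
                             rownames(randomForest::importance(fit, type = 2)))
      pred_fun <- function(Xs) stats::predict(fit, Xs, type = "prob")[, "case"]
    } else {
      dtr$..y <- as.numeric(ytr == "case")
      fit <- ranger::ranger(dependent.variable.name = "..y", data = dtr,
                            num.trees = n_trees, splitrule = "extratrees",
                            num.random.splits = 1L, importance = "impurity",
                            seed = seed, num.threads = 1L)
      raw <- fit$variable.importance
      pred_fun <- function(Xs) pmin(pmax(stats::predict(fit, Xs)$predictions, 0), 1)
    }
    list(raw = raw, pred_fun = pred_fun)
  })
  raw <- fit_env$raw %||% numeric()
  full_raw <- stats::setNames(numeric(length(marker_of)), names(marker_of))
  full_raw[names(raw)] <- pmax(raw, 0)
  scaled <- if (sum(full_raw) > 0) 100 * full_raw / sum(full_raw) else full_raw

  predict_fun <- function(X) {   # X: samples x markers, marker colnames
    Xs <- as.data.frame(X)
    names(Xs) <- names(marker_of)[match(colnames(X), marker_of)]
    as.numeric(fit_env$pred_fun(Xs))
  }
  score <- predict_fun(test$X)
  pred <- ifelse(score >= 0.5, "case", "control")
  correct <- sum(pred == test$y)
  n_test <- length(pred)
  ci <- suppressWarnings(
    stats::prop.test(correct, n_test, correct = FALSE)$conf.int)  # Wilson score
  imp <- data.frame(marker = unname(marker_of),
                    importance = unname(scaled), raw = unname(full_raw),
                    gene = unname(train$marker_to_gene[unname(marker_of)]),
                    stringsAsFactors = FALSE)
  imp <- imp[order(-imp$importance, imp$marker), , drop = FALSE]
  rownames(imp) <- NULL
  structure(list(algorithm = algorithm, group_id = train$group_id,
                 accuracy = correct / n_test,
                 ci_low = ci[1], ci_high = ci[2], n_test = n_test,
                 importances = imp, seed = seed, predict_fun = predict_fun),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s on group %s: accuracy %.4f (95%% CI %.4f-%.4f, n=%d)\n",
              x$algorithm, x$group_id, x$accuracy, x$ci_low, x$ci_high, x$n_test))
  cat("top importances:\n")
  print(utils::head(x$importances, 5))
  invisible(x)
}

#' Local surrogate explanation of one prediction
#'
#' Perturbation-based local explanation in the LIME mould: Gaussian
#' perturbations are drawn around the instance, scaled by the per-feature
#' standard deviations of the background table; the model is queried on the
#' perturbations; and a weighted ridge regression (exponential kernel on
#' the standardized distance to the instance) is fitted to the model's
#' scores. The returned weights are per unit of each feature, so a linear
#' black box is recovered exactly up to the (tiny) ridge bias. Zero-variance
#' background features are excluded with a message. Explanations depend on
#' the background only through its feature SDs, so they are invariant to
#' location shifts of any background feature.
#'
#' @param model a [train_and_score()] report, or any function mapping a
#'   samples x markers matrix to numeric scores.
#' @param instance named numeric feature vector.
#' @param background a [feature_table()] (or samples x markers matrix)
#'   supplying per-feature scales.
#' @param n_perturbations number of perturbations (default 5000).
#' @param kernel_width kernel width in standardized distance units; default
#'   `0.75 * sqrt(d)` with `d` the feature count.
#' @param n_features_out how many features to return (by |weight|).
#' @param seed integer seed.
#' @return data.frame with `marker`, `weight`, sorted by descending
#'   absolute weight.
#' @export
local_explanations <- function(model, instance, background,
                               n_perturbations = 5000L, kernel_width = NULL,
                               n_features_out = 10L, seed = 1L) {
  f <- if (inherits(model, "model_report")) model$predict_fun else model
  if (!is.function(f)) stop_arg("`model` must be a model_report or a function")
  B <- if (inherits(background, "feature_table")) background$X else background
  stopifnot(is.matrix(B))
  if (is.null(names(instance))) names(instance) <- colnames(B)
  if (!identical(sort(names(instance)), sort(colnames(B))))
    stop_arg("instance features must match the background columns")
  instance <- instance[colnames(B)]
  n_perturbations <- check_count(n_perturbations, "n_perturbations")
  sds <- apply(B, 2, stats::sd)
  if (any(sds == 0)) {
    message(sprintf("excluding %d zero-variance background feature(s)",
                    sum(sds == 0)))
  }
  use <- sds > 0
  d <- sum(use)
  if (d == 0) stop_arg("no background feature has nonzero variance")
  kw <- kernel_width %||% (0.75 * sqrt(d))
  if (kw <= 0) stop_arg("`kernel_width` must be positive")
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_perturbations * d), n_perturbations, d)
    colnames(Z) <- colnames(B)[use]
    Xp <- matrix(instance, n_perturbations, length(instance), byrow = TRUE,
                 dimnames = list(NULL, colnames(B)))
    Xp[, use] <- Xp[, use] + sweep(Z, 2, sds[use], "*")
    y <- as.numeric(f(Xp))
    wts <- exp(-rowSums(Z^2) / kw^2)          # standardized distance kernel
    D <- sweep(Z, 2, sds[use], "*")           # raw deltas -> per-unit weights
    Xd <- cbind(`(Intercept)` = 1, D)
    W <- wts
    XtWX <- crossprod(Xd * W, Xd)
    lambda <- 1e-6 * sum(W)
    pen <- diag(c(0, rep(lambda, d)))         # intercept unpenalized
    beta <- solve(XtWX + pen, crossprod(Xd * W, y))
    w <- stats::setNames(as.numeric(beta[-1]), colnames(D))
    out <- data.frame(marker = names(w), weight = unname(w),
                      stringsAsFactors = FALSE)
    out <- out[order(-abs(out$weight), out$marker), , drop = FALSE]
    rownames(out) <- NULL
    utils::head(out, check_count(n_features_out, "n_features_out"))
  })
}

#' Tally recurrent markers and genes across model reports
#'
#' Counts how often each marker appears in the top-`top_k` importances of
#' each report (markers with zero importance never count); gene tallies
#' aggregate over the gene's markers, so a gene appearing through two
#' markers in one report counts twice, matching marker-level counting.
#'
#' @param reports non-empty list of [train_and_score()] reports.
#' @param top_k importance cutoff per report.
#' @return Object of class `recurrence_tally`: list with `markers`
#'   (data.frame `marker`, `gene`, `count`) and `genes` (data.frame `gene`,
#'   `count`), both sorted by descending count.
#' @export
tally_recurrence <- function(reports, top_k = 10L) {
  if (!length(reports)) stop_arg("`reports` must be non-empty")
  stopifnot(all(vapply(reports, inherits, logical(1), "model_report")))
  top_k <- check_count(top_k, "top_k")
  picks <- lapply(reports, function(r) {
    imp <- r$importances
    imp <- imp[imp$importance > 0, , drop = FALSE]
    utils::head(imp, top_k)[, c("marker", "gene")]
  })
  all_picks <- do.call(rbind, picks)
  if (!nrow(all_picks)) {
    markers <- data.frame(marker = character(), gene = character(),
                          count = integer(), stringsAsFactors = FALSE)
    genes <- data.frame(gene = character(), count = integer(),
                        stringsAsFactors = FALSE)
  } else {
    mk <- stats::aggregate(list(count = all_picks$marker),
                           by = list(marker = all_picks$marker,
                                     gene = all_picks$gene), FUN = length)
    markers <- mk[order(-mk$count, mk$marker), , drop = FALSE]
    rownames(markers) <- NULL
    gn <- stats::aggregate(list(count = all_picks$gene),
                           by = list(gene = all_picks$gene), FUN = length)
    genes <- gn[order(-gn$count, gn$gene), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(markers = markers, genes = genes, n_reports = length(reports),
                 top_k = top_k),
            class = "recurrence_tally")
}

#' @export
print.recurrence_tally <- function(x, ...) {
  cat(sprintf("<recurrence_tally> %d reports, top %d markers each\n",
              x$n_reports, x$top_k))
  print(utils::head(x$markers, 10))
  invisible(x)
}
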