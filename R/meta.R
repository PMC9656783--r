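# Cross-dataset differential-expression meta-analysis:
# per-dataset Hedges' g -> DerSimonian-Laird random-effects pooling ->
# two-sided normal z test -> Benjamini-Hochberg FDR -> DEG selection.

#' Hedges' g standardized mean difference (case minus control)
#'
#' Standardized mean difference with the small-sample correction
#' `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)`:
#' `g = J * (mean_case - mean_control) / s_pooled`, with sampling variance
#' `var_g = (n1 + n2) / (n1 n2) + g^2 / (2 (n1 + n2))`.
#'
#' @param case,control numeric vectors, each of length >= 2 with pooled
#'   standard deviation > 0.
#' @return Object of class `effect_size`: list with `g`, `var_g`, `n_case`,
#'   `n_control`.
#' @export
hedges_g <- function(case, control) {
  case <- as.numeric(case); control <- as.numeric(control)
  n1 <- length(case); n2 <- length(control)
  if (n1 < 2 || n2 < 2) stop_arg("each group needs >= 2 values (got %d, %d)", n1, n2)
  if (anyNA(case) || anyNA(control)) stop_arg("missing values are not allowed")
  sp2 <- ((n1 - 1) * stats::var(case) + (n2 - 1) * stats::var(control)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop_arg("degenerate variance: pooled standard deviation is zero")
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  g <- J * (mean(case) - mean(control)) / sqrt(sp2)
  var_g <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  structure(list(g = g, var_g = var_g, n_case = n1, n_control = n2),
            class = "effect_size")
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance: with fixed-effect weights
#' `w = 1/var`, `Q = sum w (g - g_fe)^2`, `C = sum w - sum(w^2)/sum(w)`,
#' `tau2 = max(0, (Q - (k-1)) / C)`. Random-effects weights `1/(var + tau2)`
#' give the pooled estimate, its standard error, a z statistic and a
#' two-sided normal p-value. A single study degenerates to `pooled = g`,
#' `tau2 = 0`, `SE = sqrt(var_g)`.
#'
#' @param effects non-empty list of [hedges_g()] results (or of lists with
#'   `g` and `var_g`).
#' @param method `"random"` (DerSimonian-Laird, default) or `"fixed"`.
#' @return list with `pooled`, `tau2`, `se`, `z`, `p`, `k`.
#' @export
dl_pool <- function(effects, method = c("random", "fixed")) {
  method <- match.arg(method)
  if (!length(effects)) stop_arg("`effects` must contain at least one effect size")
  g <- vapply(effects, function(e) e$g, numeric(1))
  v <- vapply(effects, function(e) e$var_g, numeric(1))
  if (any(v <= 0)) stop_arg("all sampling variances must be > 0")
  k <- length(g)
  w <- 1 / v
  g_fe <- sum(w * g) / sum(w)
  tau2 <- 0
  if (method == "random" && k > 1) {
    Q <- sum(w * (g - g_fe)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    if (C > 0) tau2 <- max(0, (Q - (k - 1)) / C)
  }
  wr <- 1 / (v + tau2)
  pooled <- sum(wr * g) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- pooled / se
  list(pooled = pooled, tau2 = tau2, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), k = k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]) with input validation;
#' input order is preserved in the output.
#'
#' @param pvalues numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop_arg("p-values must all lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# collapse a markers x samples matrix to genes x samples
collapse_markers <- function(mat, marker_to_gene, collapse = c("max_var", "mean")) {
  collapse <- match.arg(collapse)
  genes <- unname(marker_to_gene[rownames(mat)])
  if (collapse == "max_var") {
    v <- apply(mat, 1, stats::var)
    ord <- order(genes, -v)   # per gene, highest-variance marker first
    keep <- ord[!duplicated(genes[ord])]
    out <- mat[keep, , drop = FALSE]
    rownames(out) <- genes[keep]
    out[order(rownames(out)), , drop = FALSE]
  } else {
    rowsum(mat, group = genes) / as.vector(table(genes)[sort(unique(genes))])
  }
}

#' Meta-analysis of case/control expression across datasets
#'
#' Per dataset, markers are collapsed to genes (highest-variance marker by
#' default; `collapse = "mean"` averages) and a Hedges' g (case minus
#' control) is computed per gene. Genes measured in at least `min_datasets`
#' datasets are pooled with [dl_pool()]; BH adjustment is applied across the
#' pooled genes.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param collapse marker-to-gene summarization rule.
#' @param min_datasets minimum datasets a gene must be measured in (default
#'   2; pooling a single study is vacuous but can be enabled with 1).
#' @param method pooling model, `"random"` or `"fixed"`.
#' @param log2_transform if `TRUE`, apply `log2(x + 1)` before effect sizes
#'   (for matrices on the count scale).
#' @return Object of class `meta_result`: data.frame with one row per pooled
#'   gene (`gene`, `k`, `pooled`, `tau2`, `z`, `p`, `fdr`), plus attribute
#'   `effects` (per-gene list of per-dataset effect sizes).
#' @export
meta_analyze <- function(datasets, collapse = c("max_var", "mean"),
                         min_datasets = 2L, method = c("random", "fixed"),
                         log2_transform = FALSE) {
  collapse <- match.arg(collapse); method <- match.arg(method)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "expression_dataset")))
  min_datasets <- check_count(min_datasets, "min_datasets")
  per_gene <- list()
  for (ds in datasets) {
    mat <- ds$matrix
    if (log2_transform) mat <- log2(mat + 1)
    gmat <- collapse_markers(mat, ds$marker_to_gene, collapse)
    is_case <- ds$labels == "case"
    for (g in rownames(gmat)) {
      es <- tryCatch(hedges_g(gmat[g, is_case], gmat[g, !is_case]),
                     error = function(e) NULL)   # degenerate genes skipped
      if (!is.null(es)) per_gene[[g]] <- c(per_gene[[g]], list(es))
    }
  }
  per_gene <- per_gene[lengths(per_gene) >= min_datasets]
  per_gene <- per_gene[order(names(per_gene))]
  if (!length(per_gene)) {
    res <- data.frame(gene = character(), k = integer(), pooled = numeric(),
                      tau2 = numeric(), z = numeric(), p = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE)
  } else {
    pooled <- lapply(per_gene, dl_pool, method = method)
    res <- data.frame(gene = names(per_gene),
                      k = vapply(pooled, `[[`, numeric(1), "k"),
                      pooled = vapply(pooled, `[[`, numeric(1), "pooled"),
                      tau2 = vapply(pooled, `[[`, numeric(1), "tau2"),
                      z = vapply(pooled, `[[`, numeric(1), "z"),
                      p = vapply(pooled, `[[`, numeric(1), "p"),
                      stringsAsFactors = FALSE)
    res$fdr <- bh_fdr(res$p)
  }
  rownames(res) <- NULL
  structure(res, effects = per_gene, class = c("meta_result", "data.frame"))
}

#' Select differentially expressed genes at an FDR threshold
#'
#' Keeps genes with `fdr <= alpha` (inclusive), ranked by `fdr` then by
#' descending absolute pooled effect.
#'
#' @param meta a [meta_analyze()] result.
#' @param alpha FDR threshold (default 0.001).
#' @return data.frame subset of `meta`, ranked.
#' @export
select_degs <- function(meta, alpha = 0.001) {
  stopifnot(inherits(meta, "meta_result"))
  alpha <- check_prob(alpha, "alpha")
  sel <- meta[meta$fdr <= alpha, , drop = FALSE]
  sel <- sel[order(sel$fdr, -abs(sel$pooled), sel$gene), , drop = FALSE]
  rownames(sel) <- NULL
  as.data.frame(sel)
}
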