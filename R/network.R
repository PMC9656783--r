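# Thresholded Pearson co-expression networks and hub ranking.

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the usual t test:
#' `t = r sqrt((n-2) / (1-r^2))` on `n - 2` degrees of freedom, two-sided
#' (the same test [stats::cor.test()] performs).
#'
#' @param x,y numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_arg("`x` and `y` must have equal length")
  if (length(x) < 3) stop_arg("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_arg("degenerate input: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Build a thresholded correlation network
#'
#' Computes all pairwise Pearson correlations over the rows (genes) of
#' `expr`, and keeps the edge between two genes iff `|r| >= r_min` **and**
#' `p <= p_max`. The filter is on the absolute correlation so strong
#' negative co-expression survives; edge p-values are raw (no multiplicity
#' adjustment). Zero-variance genes are skipped silently and recorded in the
#' result's `skipped` field. Edge endpoints are canonically ordered
#' (`gene_a < gene_b` lexicographically); no self edges, no duplicates.
#'
#' @param expr numeric genes x samples matrix (>= 2 genes, >= 3 samples)
#'   with gene rownames.
#' @param r_min minimum absolute correlation (default 0.5).
#' @param p_max maximum p-value (default 0.01).
#' @param group_id label carried on the network (platform group).
#' @return Object of class `corr_network`: list with `nodes`, `edges`
#'   (data.frame `gene_a`, `gene_b`, `r`, `p`, `sign`), `group_id`,
#'   `skipped`.
#' @export
build_network <- function(expr, r_min = 0.5, p_max = 0.01, group_id = "all") {
  if (!is.matrix(expr) || nrow(expr) < 2) stop_arg("`expr` needs at least 2 genes")
  if (ncol(expr) < 3) stop_arg("`expr` needs at least 3 samples")
  if (is.null(rownames(expr))) stop_arg("`expr` must have gene rownames")
  r_min <- check_prob(r_min, "r_min"); p_max <- check_prob(p_max, "p_max")
  n <- ncol(expr)
  sds <- apply(expr, 1, stats::sd)
  skipped <- rownames(expr)[sds == 0]
  ok <- expr[sds > 0, , drop = FALSE]
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (nrow(ok) >= 2) {
    R <- stats::cor(t(ok))
    tt <- abs(R) * sqrt((n - 2) / pmax(1 - R^2, 0))
    P <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
    P[abs(R) >= 1] <- 0
    idx <- which(upper.tri(R) & abs(R) >= r_min & P <= p_max, arr.ind = TRUE)
    if (nrow(idx)) {
      a <- rownames(R)[idx[, 1]]; b <- rownames(R)[idx[, 2]]
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
      r <- R[idx]
      edges <- data.frame(gene_a = a, gene_b = b, r = r, p = P[idx],
                          sign = ifelse(r >= 0, "positive", "negative"),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(nodes = rownames(expr), edges = edges, group_id = group_id,
                 skipped = skipped),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("<corr_network> group %s: %d nodes, %d edges (%d skipped degenerate)\n",
              x$group_id, length(x$nodes), nrow(x$edges), length(x$skipped)))
  invisible(x)
}

#' Rank hub genes by degree
#'
#' @param net a [build_network()] result.
#' @param top_k maximum number of genes returned; only genes with degree
#'   > 0 are listed. Ties broken lexicographically.
#' @return data.frame with `gene`, `degree`, sorted by descending degree.
#' @export
hub_rank <- function(net, top_k = 10L) {
  stopifnot(inherits(net, "corr_network"))
  top_k <- check_count(top_k, "top_k")
  if (!nrow(net$edges)) {
    return(data.frame(gene = character(), degree = integer(),
                      stringsAsFactors = FALSE))
  }
  deg <- table(c(net$edges$gene_a, net$edges$gene_b))
  df <- data.frame(gene = names(deg), degree = as.integer(deg),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, top_k)
}
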