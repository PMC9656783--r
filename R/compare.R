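# Comparing two gene lists: shared names, chromosomal proximity, shared
# loci (fixed-width bins) and shared enriched annotation terms.

#' Exact name intersection after alias canonicalization
#'
#' @param list_a,list_b character vectors of gene names.
#' @param catalog optional [gene_catalog()] used to resolve aliases to
#'   canonical symbols before intersecting.
#' @return sorted character vector.
#' @export
intersect_names <- function(list_a, list_b, catalog = NULL) {
  a <- unique(canonicalize_symbols(list_a, catalog))
  b <- unique(canonicalize_symbols(list_b, catalog))
  sort(intersect(a, b))
}

#' Cross-list gene pairs in chromosomal proximity
#'
#' All pairs (one gene from each list) on the same chromosome whose
#' start-to-start distance is strictly below `max_dist` (default 1 Mbp). A
#' gene present in both lists yields a distance-0 pair unless
#' `include_shared = FALSE`. Pairs are sorted by chromosome, then distance,
#' then gene names.
#'
#' @param list_a,list_b character vectors; every gene must be in the catalog.
#' @param catalog a [gene_catalog()].
#' @param max_dist strict distance bound in bp (default 1e6).
#' @param include_shared keep distance-0 pairs from shared genes?
#' @return data.frame with `gene_a`, `gene_b`, `chromosome`, `distance`;
#'   attributes `n_pairs`, `n_genes` (distinct genes involved, either list).
#' @export
proximity_pairs <- function(list_a, list_b, catalog, max_dist = 1e6,
                            include_shared = TRUE) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (max_dist <= 0) stop_arg("`max_dist` must be positive")
  list_a <- unique(canonicalize_symbols(list_a, catalog))
  list_b <- unique(canonicalize_symbols(list_b, catalog))
  ga <- catalog_lookup(list_a, catalog, "list A")
  gb <- catalog_lookup(list_b, catalog, "list B")
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      chromosome = character(), distance = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(ga) || !nrow(gb))
    return(structure(empty, n_pairs = 0L, n_genes = 0L))
  grid <- expand.grid(ia = seq_len(nrow(ga)), ib = seq_len(nrow(gb)))
  same <- ga$chromosome[grid$ia] == gb$chromosome[grid$ib]
  dist <- abs(ga$start[grid$ia] - gb$start[grid$ib])
  keep <- same & dist < max_dist
  if (!include_shared) keep <- keep & ga$symbol[grid$ia] != gb$symbol[grid$ib]
  df <- data.frame(gene_a = ga$symbol[grid$ia][keep],
                   gene_b = gb$symbol[grid$ib][keep],
                   chromosome = ga$chromosome[grid$ia][keep],
                   distance = dist[keep], stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$distance, df$gene_a, df$gene_b), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_pairs = nrow(df),
            n_genes = length(unique(c(df$gene_a, df$gene_b))))
}

#' Chromosomal loci shared by two gene lists
#'
#' A locus is a fixed-width bin (`floor(start / bin_size)`); a locus is
#' shared when at least one gene from each list falls in it.
#'
#' @inheritParams proximity_pairs
#' @param bin_size bin width in bp (> 0, default 1 Mbp).
#' @return data.frame with `chromosome`, `bin`, sorted.
#' @export
shared_loci <- function(list_a, list_b, catalog, bin_size = 1e6) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (bin_size <= 0) stop_arg("`bin_size` must be > 0")
  bins <- function(lst) {
    g <- catalog_lookup(unique(canonicalize_symbols(lst, catalog)), catalog)
    unique(paste(g$chromosome, floor(g$start / bin_size), sep = ":"))
  }
  shared <- intersect(bins(list_a), bins(list_b))
  if (!length(shared)) {
    return(data.frame(chromosome = character(), bin = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(sort(shared), ":", fixed = TRUE)
  data.frame(chromosome = vapply(parts, `[[`, character(1), 1),
             bin = as.integer(vapply(parts, `[[`, character(1), 2)),
             stringsAsFactors = FALSE)
}

#' Annotation terms significantly enriched in both lists
#'
#' Terms with BH-adjusted p <= `fdr_max` in both enrichment tables, grouped
#' by the annotation category. Both enrichments must come from the same
#' annotation collection (checked via a collection fingerprint).
#'
#' @param enrich_a,enrich_b two [enrich()] results over the same collection.
#' @param fdr_max adjusted-p threshold (default 0.05).
#' @return named list: category -> sorted character vector of term ids.
#' @export
shared_terms <- function(enrich_a, enrich_b, fdr_max = 0.05) {
  stopifnot(inherits(enrich_a, "enrichment_result"),
            inherits(enrich_b, "enrichment_result"))
  fdr_max <- check_prob(fdr_max, "fdr_max")
  ha <- attr(enrich_a, "collection_hash"); hb <- attr(enrich_b, "collection_hash")
  if (!is.null(ha) && !is.null(hb) && !identical(ha, hb))
    stop_arg("enrichments come from different annotation collections")
  sig_a <- enrich_a[enrich_a$fdr <= fdr_max, c("term_id", "category")]
  sig_b <- enrich_b[enrich_b$fdr <= fdr_max, c("term_id", "category")]
  common <- merge(sig_a, sig_b)
  out <- split(common$term_id, common$category)
  lapply(out[order(names(out))], sort)
}

#' Full comparison of two gene lists
#'
#' Convenience wrapper producing shared names, proximity pairs (with both
#' the pair count and the distinct-gene count, since either reading of
#' "close genes" is of interest), shared loci and shared enriched terms.
#'
#' @inheritParams proximity_pairs
#' @param bin_size locus bin width in bp.
#' @param enrich_a,enrich_b optional [enrich()] results for the two lists.
#' @param fdr_max threshold for [shared_terms()].
#' @return list of class `comparison_report`.
#' @export
compare_gene_lists <- function(list_a, list_b, catalog, max_dist = 1e6,
                               bin_size = 1e6, enrich_a = NULL,
                               enrich_b = NULL, fdr_max = 0.05) {
  pairs <- proximity_pairs(list_a, list_b, catalog, max_dist = max_dist)
  terms <- if (!is.null(enrich_a) && !is.null(enrich_b))
    shared_terms(enrich_a, enrich_b, fdr_max) else list()
  structure(list(
    shared_names = intersect_names(list_a, list_b, catalog),
    proximity_pairs = pairs,
    n_proximity_pairs = attr(pairs, "n_pairs"),
    n_proximity_genes = attr(pairs, "n_genes"),
    shared_loci = shared_loci(list_a, list_b, catalog, bin_size = bin_size),
    shared_terms = terms), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(paste0("<comparison_report> %d shared names, %d proximity pairs",
                     " (%d genes), %d shared loci, %d shared term categories\n"),
              length(x$shared_names), x$n_proximity_pairs,
              x$n_proximity_genes, nrow(x$shared_loci),
              length(x$shared_terms)))
  invisible(x)
}
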