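# Overlap-ratio gene-set enrichment against GMT annotation collections.
#
# Two descriptive ratios accompany each term: the *share* ratio, the
# percentage of the studied list that belongs to the term
# (100 |L n T| / |L|), and the *intersection* ratio, the percentage of the
# term's annotated genes found in the list (100 |L n T| / |T|). The test
# statistic is the one-sided hypergeometric (Fisher) upper tail; the
# reported FDR column is -log10 of the BH-adjusted p.

#' Overlap, share and intersection ratios
#'
#' @param gene_list,term_members non-empty character vectors (sets).
#' @return list with `overlap` (count), `share` and `intersection`
#'   (percentages, full precision; round only when serializing).
#' @export
overlap_ratios <- function(gene_list, term_members) {
  gene_list <- unique(gene_list); term_members <- unique(term_members)
  if (!length(gene_list)) stop_arg("`gene_list` must be non-empty")
  if (!length(term_members)) stop_arg("`term_members` must be non-empty")
  ov <- length(intersect(gene_list, term_members))
  list(overlap = ov,
       share = 100 * ov / length(gene_list),
       intersection = 100 * ov / length(term_members))
}

#' Hypergeometric upper-tail p-value
#'
#' `P(X >= overlap)` where `X` is the overlap of a random `list_size`-subset
#' of the background with a fixed term of `term_size` genes.
#'
#' @param overlap observed overlap (`<= min(list_size, term_size)`).
#' @param list_size,term_size,background_size set sizes (`list_size`,
#'   `term_size <= background_size`).
#' @return probability.
#' @export
hypergeom_p <- function(overlap, list_size, term_size, background_size) {
  overlap <- check_count(overlap, "overlap", min = 0L)
  list_size <- check_count(list_size, "list_size", min = 0L)
  term_size <- check_count(term_size, "term_size", min = 0L)
  background_size <- check_count(background_size, "background_size", min = 0L)
  if (overlap > min(list_size, term_size) ||
      list_size > background_size || term_size > background_size)
    stop_arg("inconsistent counts: overlap=%d list=%d term=%d background=%d",
             overlap, list_size, term_size, background_size)
  stats::phyper(overlap - 1, term_size, background_size - term_size,
                list_size, lower.tail = FALSE)
}

#' Enrichment of a gene list against annotation sets
#'
#' Restricts the list to the annotated background (genes outside it are
#' dropped with a warning and recorded in the `dropped` attribute), tests
#' every term of size >= `min_term_size` with nonzero overlap, applies BH
#' adjustment across the tested terms, and sorts by descending
#' `fdr_neglog10 = -log10(adjusted p)`.
#'
#' @param gene_list character vector of gene symbols.
#' @param sets an [annotation_sets()].
#' @param min_term_size smallest term tested.
#' @return Object of class `enrichment_result`: data.frame with `term_id`,
#'   `term_name`, `category`, `overlap`, `list_size`, `term_size`, `share`,
#'   `intersection`, `p`, `fdr`, `fdr_neglog10`; attributes `list_size`
#'   (effective), `dropped`, `collection_hash`.
#' @export
enrich <- function(gene_list, sets, min_term_size = 5L) {
  stopifnot(inherits(sets, "annotation_sets"))
  min_term_size <- check_count(min_term_size, "min_term_size")
  gene_list <- unique(gene_list)
  dropped <- setdiff(gene_list, sets$background)
  eff <- intersect(gene_list, sets$background)
  if (length(dropped))
    warning(sprintf("%d gene(s) outside the annotated background were dropped",
                    length(dropped)), call. = FALSE)
  if (!length(eff)) stop_arg("no genes of the list are in the annotated background")
  bg_n <- length(sets$background)
  eligible <- lengths(sets$terms$members) >= min_term_size
  rows <- lapply(which(eligible), function(i) {
    mem <- sets$terms$members[[i]]
    rat <- overlap_ratios(eff, mem)
    if (rat$overlap == 0) return(NULL)
    data.frame(term_id = sets$terms$term_id[i],
               term_name = sets$terms$term_name[i],
               category = sets$terms$category[i],
               overlap = rat$overlap, list_size = length(eff),
               term_size = length(mem),
               share = rat$share, intersection = rat$intersection,
               p = hypergeom_p(rat$overlap, length(eff), length(mem), bg_n),
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(term_id = character(), term_name = character(),
                       category = character(), overlap = integer(),
                       list_size = integer(), term_size = integer(),
                       share = numeric(), intersection = numeric(),
                       p = numeric(), fdr = numeric(),
                       fdr_neglog10 = numeric(), stringsAsFactors = FALSE)
  } else {
    rows$fdr <- bh_fdr(rows$p)
    rows$fdr_neglog10 <- -log10(rows$fdr)
    rows <- rows[order(-rows$fdr_neglog10, rows$p, rows$term_id), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(rows, list_size = length(eff), dropped = dropped,
            collection_hash = object_hash(sets$terms[c("term_id", "category")]),
            class = c("enrichment_result", "data.frame"))
}

#' Serialize an enrichment table
#'
#' Writes a TSV mirroring the reporting convention: term, category,
#' `fdr_neglog10`, share and intersection percentages (rounded to 2
#' decimals at this point only), plus overlap, sizes and the raw p.
#'
#' @param result an [enrich()] result.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_enrichment <- function(result, path) {
  df <- as.data.frame(result)
  df$share <- round(df$share, 2)
  df$intersection <- round(df$intersection, 2)
  df$fdr_neglog10 <- round(df$fdr_neglog10, 2)
  write_tsv(df[, c("term_id", "term_name", "category", "fdr_neglog10",
                   "share", "intersection", "overlap", "list_size",
                   "term_size", "p")], path)
  invisible(path)
}
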