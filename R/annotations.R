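# Annotation term collections (GMT-style), with a synthetic generator.

#' Annotation set collection
#'
#' @param terms data.frame with columns `term_id`, `term_name`, `category`;
#'   plus a list-column `members` of character vectors (or pass `members` as
#'   a separate named list).
#' @param background character vector: the annotated gene universe.
#' @return Object of class `annotation_sets`.
#' @export
annotation_sets <- function(terms, background) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "term_name", "category", "members") %in% names(terms)))
  if (anyDuplicated(terms$term_id)) stop_arg("term ids must be unique")
  if (any(lengths(terms$members) == 0)) stop_arg("term member sets must be non-empty")
  out <- setdiff(unlist(terms$members, use.names = FALSE), background)
  if (length(out))
    stop_arg("term members outside the background: %s",
             paste(utils::head(out, 5), collapse = ", "))
  structure(list(terms = terms, background = unique(background)),
            class = "annotation_sets")
}

#' @export
print.annotation_sets <- function(x, ...) {
  cat(sprintf("<annotation_sets> %d terms (%s), background of %d genes\n",
              nrow(x$terms),
              paste(sprintf("%s: %d", names(table(x$terms$category)),
                            table(x$terms$category)), collapse = ", "),
              length(x$background)))
  invisible(x)
}

#' Simulate annotation term sets
#'
#' Draws `n_terms` terms with sizes uniform in `size_range`, members sampled
#' from the catalog (the background is the whole catalog), and categories
#' cycled over `categories`. An optional `enriched_term_spec =
#' list(term_id=, genes=, size=, avoid=)` plants a term guaranteed to
#' contain the listed genes, padded with random genes up to `size` (never
#' drawn from `avoid`), so enrichment recovery is testable by construction.
#'
#' @param catalog a [gene_catalog()] (non-empty).
#' @param n_terms number of terms (>= 1).
#' @param size_range integer pair `c(min, max)`; `max` <= catalog size.
#' @param enriched_term_spec optional planted term (see above).
#' @param categories category labels cycled over the terms.
#' @param seed integer seed.
#' @return An [annotation_sets()].
#' @export
generate_annotations <- function(catalog, n_terms, size_range,
                                 enriched_term_spec = NULL,
                                 categories = c("GO", "pathway", "KEGG"),
                                 seed = 1L) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (nrow(catalog$genes) == 0) stop_arg("catalog must be non-empty")
  n_terms <- check_count(n_terms, "n_terms")
  genes <- catalog$genes$symbol
  size_range <- as.integer(size_range)
  if (length(size_range) != 2 || size_range[1] < 1 || size_range[2] < size_range[1])
    stop_arg("`size_range` must be c(min, max) with 1 <= min <= max")
  if (size_range[2] > length(genes))
    stop_arg("max term size (%d) exceeds catalog size (%d)",
             size_range[2], length(genes))
  with_seed(seed, {
    size_choices <- seq(size_range[1], size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_terms, replace = TRUE)]
    members <- lapply(sizes, function(s) sort(sample(genes, s)))
    terms <- data.frame(term_id = sprintf("T%04d", seq_len(n_terms)),
                        term_name = sprintf("synthetic term %d", seq_len(n_terms)),
                        category = rep_len(categories, n_terms),
                        stringsAsFactors = FALSE)
    terms$members <- members
    if (!is.null(enriched_term_spec)) {
      spec_genes <- enriched_term_spec$genes
      if (!all(spec_genes %in% genes))
        stop_arg("enriched_term_spec genes must be in the catalog")
      size <- as.integer(enriched_term_spec$size %||% length(spec_genes))
      size <- max(size, length(spec_genes))
      avoid <- union(spec_genes, enriched_term_spec$avoid %||% character())
      pad <- sample(setdiff(genes, avoid), size - length(spec_genes))
      row <- data.frame(term_id = enriched_term_spec$term_id,
                        term_name = enriched_term_spec$term_name %||% enriched_term_spec$term_id,
                        category = enriched_term_spec$category %||% categories[1],
                        stringsAsFactors = FALSE)
      row$members <- list(sort(c(spec_genes, pad)))
      terms <- rbind(terms, row)
    }
    annotation_sets(terms, genes)
  })
}

#' Write / read annotation sets in GMT format
#'
#' One term per line: `term_id TAB category|term_name TAB gene1 TAB ...`.
#' On read, a description without a `|` yields category `"uncategorized"`.
#'
#' @param sets an [annotation_sets()].
#' @param path file path.
#' @param background background to attach on read; defaults to the union of
#'   all member sets.
#' @return the path (writer); an [annotation_sets()] (reader).
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "annotation_sets"))
  lines <- vapply(seq_len(nrow(sets$terms)), function(i) {
    t <- sets$terms[i, ]
    paste(c(t$term_id, paste0(t$category, "|", t$term_name), t$members[[1]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  desc <- vapply(parts, `[[`, character(1), 2)
  has_cat <- grepl("|", desc, fixed = TRUE)
  terms <- data.frame(
    term_id = vapply(parts, `[[`, character(1), 1),
    term_name = ifelse(has_cat, sub("^[^|]*\\|", "", desc), desc),
    category = ifelse(has_cat, sub("\\|.*$", "", desc), "uncategorized"),
    stringsAsFactors = FALSE)
  terms$members <- lapply(parts, function(p) unique(p[-(1:2)]))
  annotation_sets(terms, background %||% unique(unlist(terms$members)))
}
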