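# Dictionary-based gene-mention mining of an abstract corpus.
#
# Matching is exact, case-sensitive and token-level: gene symbols are
# case-significant (SET vs "set"), and no NER model is assumed. The counting
# unit is the article — a gene is counted once per article no matter how
# often it recurs in the text.

#' Default stop phrases and mention blacklist
#'
#' `default_stop_phrases()` is a small common-English stopword list removed
#' (case-insensitively) during tokenization. `default_blacklist()` lists gene
#' symbols that are ordinary English words and therefore unusable for
#' dictionary matching; both are configurable in the calling functions.
#'
#' @return character vector.
#' @export
default_stop_phrases <- function() {
  c("the", "a", "an", "of", "and", "or", "in", "on", "to", "for", "with",
    "is", "are", "was", "were", "be", "been", "by", "as", "at", "that",
    "this", "these", "those", "from", "it", "its", "we", "our", "their",
    "has", "have", "had", "not", "no", "but", "than", "then", "which")
}

#' @rdname default_stop_phrases
#' @export
default_blacklist <- function() {
  c("SET", "CAT", "MET", "CAST", "REST", "IMPACT", "LARGE", "SHE", "WAS",
    "ICE", "MICE", "ACHE", "CLOCK", "APEX", "FATE", "GIF", "PIGS", "COPE",
    "CELL", "MARS", "ITCH", "FLOT1")
}

#' Tokenize abstract text
#'
#' Splits on non-alphanumeric boundaries while keeping hyphens inside tokens
#' (so `HLA-DRB1` survives as one token), removes stop phrases
#' case-insensitively, and collapses runs of consecutive identical tokens.
#' Case is preserved on surviving tokens. Total function: empty input gives
#' an empty token vector.
#'
#' @param text a character scalar.
#' @param stop_phrases character vector of tokens to drop (case-insensitive).
#' @return character vector of tokens.
#' @export
normalize_text <- function(text, stop_phrases = default_stop_phrases()) {
  if (length(text) != 1L) stop_arg("`text` must be a single string")
  if (is.na(text) || !nzchar(text)) return(character())
  tokens <- strsplit(text, "[^[:alnum:]-]+")[[1]]
  tokens <- gsub("^-+|-+$", "", tokens)     # strip dangling hyphens
  tokens <- tokens[nzchar(tokens)]
  if (length(stop_phrases) && length(tokens))
    tokens <- tokens[!(tolower(tokens) %in% tolower(stop_phrases))]
  if (length(tokens) > 1L)                   # collapse consecutive duplicates
    tokens <- tokens[c(TRUE, tokens[-1L] != tokens[-length(tokens)])]
  tokens
}

#' Match tokens against a gene catalog
#'
#' A symbol is reported iff some token equals the symbol, or one of its
#' aliases, case-sensitively, and the matched string is not blacklisted.
#' Aliases resolve to their canonical symbol.
#'
#' @param tokens character vector from [normalize_text()].
#' @param catalog a non-empty [gene_catalog()].
#' @param blacklist matched strings to ignore (exact, case-sensitive).
#' @return sorted character vector of canonical symbols (a set).
#' @export
match_genes <- function(tokens, catalog, blacklist = default_blacklist()) {
  stopifnot(inherits(catalog, "gene_catalog"))
  if (nrow(catalog$genes) == 0) stop_arg("catalog must be non-empty")
  if (!length(tokens)) return(character())
  tokens <- setdiff(tokens, blacklist)
  hits <- intersect(tokens, catalog$genes$symbol)
  via_alias <- unname(catalog$aliases[intersect(tokens, names(catalog$aliases))])
  sort(unique(c(hits, via_alias)))
}

#' Build a gene-mention index over a corpus
#'
#' Scans every article with [normalize_text()] + [match_genes()] and records,
#' per gene, the set of article ids mentioning it (deduplicated within
#' article).
#'
#' @param corpus a [synthetic_corpus()] or data.frame with columns
#'   `article_id`, `text`.
#' @param catalog a [gene_catalog()].
#' @param stop_phrases,blacklist see [normalize_text()], [match_genes()].
#' @return Object of class `mention_index`: list with `per_gene` (named list
#'   of sorted article-id vectors) and `n_articles_scanned`.
#' @export
build_index <- function(corpus, catalog,
                        stop_phrases = default_stop_phrases(),
                        blacklist = default_blacklist()) {
  articles <- if (inherits(corpus, "synthetic_corpus")) corpus$articles else corpus
  if (!is.data.frame(articles) || !all(c("article_id", "text") %in% names(articles)))
    stop_arg("corpus must provide article_id and text columns")
  per_gene <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(articles))) {
    id <- articles$article_id[i]
    txt <- articles$text[i]
    if (is.na(id) || is.na(txt))
      stop(sprintf("unreadable corpus record at row %d (article_id=%s)", i, id))
    genes <- match_genes(normalize_text(txt, stop_phrases), catalog, blacklist)
    for (g in genes) assign(g, c(get0(g, per_gene, ifnotfound = character()), id),
                            envir = per_gene)
  }
  pg <- as.list(per_gene)
  if (length(pg)) pg <- lapply(pg[order(names(pg))], function(v) sort(unique(v)))
  structure(list(per_gene = pg, n_articles_scanned = nrow(articles)),
            class = "mention_index")
}

#' @export
print.mention_index <- function(x, ...) {
  cat(sprintf("<mention_index> %d genes mentioned across %d scanned articles\n",
              length(x$per_gene), x$n_articles_scanned))
  invisible(x)
}

#' Filter the mention index to frequently mentioned genes
#'
#' Keeps genes mentioned in strictly more than `min_articles` articles
#' ("more than 50 articles" is the conventional literature-frequency filter
#' and the default). Rows are sorted by descending article count, ties
#' broken lexicographically by symbol.
#'
#' @param index a [build_index()] result.
#' @param min_articles strict lower bound on the article count (>= 0).
#' @return Object of class `frequency_table`: data.frame with `symbol`,
#'   `article_count`, plus attribute `threshold_used`.
#' @export
filter_frequent <- function(index, min_articles = 50L) {
  stopifnot(inherits(index, "mention_index"))
  min_articles <- check_count(min_articles, "min_articles", min = 0L)
  counts <- lengths(index$per_gene)
  if (is.null(names(counts))) names(counts) <- character(length(counts))
  keep <- counts > min_articles
  df <- data.frame(symbol = names(counts)[keep],
                   article_count = as.integer(unname(counts[keep])),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$article_count, df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, threshold_used = min_articles,
            class = c("frequency_table", "data.frame"))
}

#' Chromosomal distribution of frequent genes
#'
#' Counts the table's genes per chromosome; chromosomes present in the
#' catalog but holding none of the genes are reported with count 0, so the
#' counts always sum to the number of table rows.
#'
#' @param table a [filter_frequent()] result (or data.frame with `symbol`).
#' @param catalog a [gene_catalog()] covering every table symbol.
#' @return named integer vector, chromosome -> gene count.
#' @export
chromosome_distribution <- function(table, catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  hits <- catalog_lookup(table$symbol, catalog, "frequency table")
  chroms <- unique(catalog$genes$chromosome)
  counts <- table(factor(hits$chromosome, levels = chroms))
  stats::setNames(as.integer(counts), chroms)
}
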