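# Synthetic abstract corpora with planted gene mentions.
#
# The text model is deliberately simple: each article is a bag of decoy tokens
# drawn from a fixed common-English vocabulary, with planted gene symbols
# inserted as standalone tokens. Downstream mining is token-level, so
# token-level realism is all the recovery tests need.

# fixed common-English decoy vocabulary (lowercase on purpose: gene matching
# is case-sensitive, so decoys never collide with upper-case symbols)
common_english_words <- c(
  "the", "of", "and", "in", "to", "with", "for", "was", "were", "that",
  "patients", "study", "results", "analysis", "levels", "expression",
  "associated", "risk", "group", "control", "clinical", "significant",
  "increased", "decreased", "compared", "between", "among", "during",
  "treatment", "disease", "diabetes", "insulin", "glucose", "blood",
  "serum", "plasma", "cells", "tissue", "role", "function", "effect",
  "effects", "observed", "showed", "found", "report", "data", "methods",
  "conclusion", "background", "objective", "evidence", "factors", "type",
  "model", "models", "cohort", "population", "subjects", "healthy",
  "age", "higher", "lower", "respectively", "however", "these", "both",
  "also", "further", "novel", "potential", "may", "suggest", "suggests",
  "related", "association", "signaling", "pathway", "pathways", "protein",
  "proteins", "receptor", "response", "regulation", "metabolic", "chronic",
  "human", "mouse", "animal", "studies", "measured", "after", "before",
  "years", "months", "weeks", "daily", "total", "mean", "median", "range",
  "versus", "while", "within", "without", "under", "over", "about", "into",
  "several", "common", "rare", "variant", "variants", "allele", "genetic",
  "genome", "wide", "screening", "identified", "reported", "literature"
)

#' Synthetic corpus constructor
#'
#' @param articles data.frame with columns `article_id`, `text`.
#' @param truth named list: gene symbol -> character vector of article ids in
#'   which that gene was planted.
#' @param ambiguous named list recording ambiguity decoys: token -> article
#'   ids where the token was planted as plain text (not a gene mention).
#' @return Object of class `synthetic_corpus`.
#' @export
synthetic_corpus <- function(articles, truth = list(), ambiguous = list()) {
  stopifnot(is.data.frame(articles),
            all(c("article_id", "text") %in% names(articles)))
  if (anyDuplicated(articles$article_id)) stop_arg("article ids must be unique")
  bad <- setdiff(unlist(truth, use.names = FALSE), articles$article_id)
  if (length(bad)) stop_arg("truth refers to unknown article ids: %s",
                            paste(utils::head(bad, 5), collapse = ", "))
  structure(list(articles = articles, truth = truth, ambiguous = ambiguous),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d articles, %d planted genes, %d ambiguity decoys\n",
              nrow(x$articles), length(x$truth), length(x$ambiguous)))
  invisible(x)
}

#' Simulate an abstract corpus with planted gene mentions
#'
#' For every entry of `mention_plan` the symbol is planted, as a standalone
#' token, into exactly that many distinct articles (chosen at random), and the
#' article ids are recorded as ground truth. Remaining text is decoy tokens
#' sampled from a fixed common-English vocabulary. Ambiguity decoys — strings
#' that happen to equal gene symbols or aliases but are meant as plain
#' English — can be planted too; they are recorded separately in
#' `$ambiguous`, never in `$truth`, so miner blacklist behaviour is testable.
#'
#' @param catalog a [gene_catalog()]; every planned symbol must be in it.
#' @param n_articles number of articles.
#' @param mention_plan named integer vector: symbol -> number of articles that
#'   must mention it. Counts of 0 are allowed (the gene then never occurs).
#' @param decoy_vocab_size how many common-English words to use as decoys.
#' @param words_per_article decoy tokens per article.
#' @param ambiguous_tokens character vector of gene symbols/aliases to plant
#'   as plain-English decoys in ~10% of articles.
#' @param seed integer seed.
#' @return A [synthetic_corpus()].
#' @export
generate_corpus <- function(catalog, n_articles, mention_plan,
                            decoy_vocab_size = 80L, words_per_article = 30L,
                            ambiguous_tokens = character(), seed = 1L) {
  stopifnot(inherits(catalog, "gene_catalog"))
  n_articles <- check_count(n_articles, "n_articles")
  if (length(mention_plan) && is.null(names(mention_plan)))
    stop_arg("`mention_plan` must be named by gene symbol")
  plan <- vapply(mention_plan, function(x) check_count(x, "mention_plan", min = 0L), integer(1))
  unknown <- setdiff(names(plan), catalog$genes$symbol)
  if (length(unknown))
    stop_arg("mention_plan symbols absent from catalog: %s", paste(unknown, collapse = ", "))
  if (any(plan > n_articles))
    stop_arg("mention_plan counts may not exceed n_articles (%d)", n_articles)
  decoy_vocab_size <- check_count(decoy_vocab_size, "decoy_vocab_size", min = 0L)
  vocab <- utils::head(common_english_words,
                       max(1L, min(decoy_vocab_size, length(common_english_words))))

  with_seed(seed, {
    ids <- sprintf("A%05d", seq_len(n_articles))
    planted <- vector("list", n_articles)  # tokens to insert per article
    names(planted) <- ids
    truth <- list()
    for (sym in names(plan)) {
      k <- plan[[sym]]
      chosen <- if (k > 0) sort(sample(ids, k)) else character()
      truth[[sym]] <- chosen
      for (a in chosen) planted[[a]] <- c(planted[[a]], sym)
    }
    ambiguous <- list()
    for (tok in ambiguous_tokens) {
      n_amb <- max(1L, round(0.1 * n_articles))
      chosen <- sort(sample(ids, n_amb))
      ambiguous[[tok]] <- chosen
      for (a in chosen) planted[[a]] <- c(planted[[a]], tok)
    }
    text <- vapply(ids, function(a) {
      toks <- sample(vocab, words_per_article, replace = TRUE)
      ins <- planted[[a]]
      if (length(ins)) { # splice planted tokens at random positions
        pos <- sort(sample.int(length(toks) + length(ins), length(ins)))
        out <- character(length(toks) + length(ins))
        out[pos] <- sample(ins)
        out[-pos] <- toks
        toks <- out
      }
      paste0(paste(toks, collapse = " "), ".")
    }, character(1))
    synthetic_corpus(data.frame(article_id = ids, text = unname(text),
                                stringsAsFactors = FALSE),
                     truth = truth, ambiguous = ambiguous)
  })
}

#' Write / read a corpus as two-column TSV
#'
#' Format: `article_id TAB text`, UTF-8, with a header line.
#'
#' @param corpus a [synthetic_corpus()] or data.frame with `article_id`, `text`.
#' @param path file path.
#' @return the path (writer) / a data.frame with `article_id`, `text` (reader).
#' @export
write_corpus <- function(corpus, path) {
  df <- if (inherits(corpus, "synthetic_corpus")) corpus$articles else corpus
  write_tsv(df[, c("article_id", "text")], path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  df <- read_tsv(path)
  if (!all(c("article_id", "text") %in% names(df)))
    stop_arg("corpus file %s must have columns article_id, text", path)
  df
}

#' Read a MEDLINE-like plain-text corpus
#'
#' Parses records with `PMID-` and `AB  -` fields (continuation lines
#' indented with spaces are appended to the running abstract).
#'
#' @param path file path.
#' @return data.frame with `article_id`, `text`.
#' @export
read_medline <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ids <- character(); texts <- character()
  cur_id <- NA_character_; cur_ab <- NULL; in_ab <- FALSE
  flush <- function() {
    if (!is.na(cur_id)) {
      ids <<- c(ids, cur_id)
      texts <<- c(texts, paste(cur_ab %||% "", collapse = " "))
    }
  }
  for (ln in lines) {
    if (grepl("^PMID-", ln)) {
      flush()
      cur_id <- trimws(sub("^PMID-", "", ln)); cur_ab <- NULL; in_ab <- FALSE
    } else if (grepl("^AB  -", ln)) {
      cur_ab <- c(cur_ab, trimws(sub("^AB  -", "", ln))); in_ab <- TRUE
    } else if (in_ab && grepl("^\\s+", ln)) {
      cur_ab <- c(cur_ab, trimws(ln))
    } else {
      in_ab <- FALSE
    }
  }
  flush()
  if (!length(ids)) stop_arg("no PMID- records found in %s", path)
  data.frame(article_id = ids, text = texts, stringsAsFactors = FALSE)
}
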