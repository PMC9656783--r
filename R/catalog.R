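#' Gene catalog
#'
#' A gene catalog holds the shared symbol/coordinate reference used by the
#' mention miner, the proximity comparison and the chromosome distribution
#' summary: one row per gene with a unique symbol, a chromosome label and a
#' start coordinate (bp), plus an alias table mapping alternative names to
#' canonical symbols.
#'
#' @param genes data.frame with columns `symbol`, `chromosome`, `start`.
#' @param aliases named character vector: names are alias strings, values are
#'   the canonical symbols they resolve to. May be empty.
#' @return An object of class `gene_catalog`.
#' @export
gene_catalog <- function(genes, aliases = character()) {
  stopifnot(is.data.frame(genes),
            all(c("symbol", "chromosome", "start") %in% names(genes)))
  genes <- genes[, c("symbol", "chromosome", "start")]
  genes$symbol <- as.character(genes$symbol)
  genes$chromosome <- as.character(genes$chromosome)
  genes$start <- as.numeric(genes$start)
  if (anyDuplicated(genes$symbol)) stop_arg("catalog symbols must be unique")
  if (any(genes$start < 0)) stop_arg("catalog start positions must be >= 0")
  aliases <- as.character(aliases) |> stats::setNames(names(aliases))
  if (length(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases))))
      stop_arg("aliases must be a named character vector (alias -> symbol)")
    if (any(names(aliases) %in% genes$symbol))
      stop_arg("aliases must be disjoint from catalog symbols")
    if (anyDuplicated(names(aliases))) stop_arg("alias names must be unique")
    if (!all(aliases %in% genes$symbol))
      stop_arg("every alias must resolve to a catalog symbol")
  }
  structure(list(genes = genes, aliases = aliases), class = "gene_catalog")
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat(sprintf("<gene_catalog> %d genes on %d chromosomes, %d aliases\n",
              nrow(x$genes), length(unique(x$genes$chromosome)),
              length(x$aliases)))
  invisible(x)
}

#' Simulate a gene catalog
#'
#' Draws `n_genes` symbols with chromosome labels `chr1..chrN` and uniform
#' start positions. When `n_genes >= 2` the first two genes are placed on the
#' same chromosome less than 1 Mbp apart, and when `n_genes >= 3` a third gene
#' is placed far (>= 10 Mbp) from the first, so chromosomal-proximity logic
#' always has both a near and a far pair to exercise. A fraction of genes
#' receive one alias (`<symbol>ALT`), disjoint from the symbol set.
#'
#' @param n_genes number of genes (>= 1).
#' @param n_chromosomes number of chromosome labels (>= 1).
#' @param seed integer seed; equal seeds give identical catalogs.
#' @param alias_rate fraction of genes given one alias.
#' @param chrom_span coordinate span (bp) per chromosome.
#' @return A [gene_catalog()].
#' @export
generate_catalog <- function(n_genes, n_chromosomes = 22L, seed = 1L,
                             alias_rate = 0.25, chrom_span = 2e8) {
  n_genes <- check_count(n_genes, "n_genes")
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes")
  alias_rate <- check_prob(alias_rate, "alias_rate")
  with_seed(seed, {
    symbol <- sprintf("G%04d", seq_len(n_genes))
    chromosome <- paste0("chr", sample.int(n_chromosomes, n_genes, replace = TRUE))
    start <- floor(stats::runif(n_genes, 0, chrom_span))
    if (n_genes >= 2) { # guarantee one pair closer than 1 Mbp
      chromosome[2] <- chromosome[1]
      start[2] <- start[1] + sample(1e4:9e5, 1)
    }
    if (n_genes >= 3) { # and one pair on the same chromosome much farther away
      chromosome[3] <- chromosome[1]
      start[3] <- start[1] + 1e7 + sample(0:1e7, 1)
    }
    has_alias <- stats::runif(n_genes) < alias_rate
    aliases <- stats::setNames(symbol[has_alias], paste0(symbol[has_alias], "ALT"))
    gene_catalog(data.frame(symbol = symbol, chromosome = chromosome,
                            start = start, stringsAsFactors = FALSE),
                 aliases)
  })
}

#' Resolve aliases to canonical symbols
#'
#' Maps any alias in `symbols` to its canonical catalog symbol; strings that
#' are neither a symbol nor an alias pass through unchanged.
#'
#' @param symbols character vector of gene names.
#' @param catalog a [gene_catalog()] (or `NULL` for a no-op).
#' @return character vector of the same length.
#' @export
canonicalize_symbols <- function(symbols, catalog = NULL) {
  if (is.null(catalog)) return(symbols)
  stopifnot(inherits(catalog, "gene_catalog"))
  hit <- match(symbols, names(catalog$aliases))
  symbols[!is.na(hit)] <- unname(catalog$aliases[hit[!is.na(hit)]])
  symbols
}

catalog_lookup <- function(symbols, catalog, what = "gene list") {
  idx <- match(symbols, catalog$genes$symbol)
  if (anyNA(idx)) {
    stop_arg("%s contains symbols absent from the catalog: %s", what,
             paste(symbols[is.na(idx)], collapse = ", "))
  }
  catalog$genes[idx, , drop = FALSE]
}

#' Write / read a gene catalog
#'
#' The catalog is serialized as a BED-like 4-column table
#' (chromosome, start, start+1, symbol) plus an alias sidecar TSV.
#'
#' @param catalog a [gene_catalog()].
#' @param bed_path path for the BED-like table.
#' @param alias_path path for the alias sidecar (alias TAB symbol).
#' @return `bed_path`, invisibly (writer); a [gene_catalog()] (reader).
#' @export
write_catalog <- function(catalog, bed_path, alias_path = paste0(bed_path, ".aliases.tsv")) {
  stopifnot(inherits(catalog, "gene_catalog"))
  g <- catalog$genes
  bed <- data.frame(chrom = g$chromosome, start = format(g$start, scientific = FALSE, trim = TRUE),
                    end = format(g$start + 1, scientific = FALSE, trim = TRUE),
                    name = g$symbol)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ali <- data.frame(alias = names(catalog$aliases),
                    symbol = unname(catalog$aliases))
  write_tsv(ali, alias_path)
  invisible(bed_path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(bed_path, alias_path = paste0(bed_path, ".aliases.tsv")) {
  bed <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           stringsAsFactors = FALSE)
  aliases <- character()
  if (file.exists(alias_path)) {
    ali <- read_tsv(alias_path)
    if (nrow(ali)) aliases <- stats::setNames(ali$symbol, ali$alias)
  }
  gene_catalog(data.frame(symbol = bed$name, chromosome = bed$chrom,
                          start = bed$start, stringsAsFactors = FALSE),
               aliases)
}
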