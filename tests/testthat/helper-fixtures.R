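# small fixtures built in code

tiny_catalog <- function() {
  gene_catalog(
    data.frame(symbol = c("HNF4A", "TCF7L2", "HLA-DRB1", "TIMP1", "POMC", "SET"),
               chromosome = c("chr20", "chr10", "chr6", "chrX", "chr2", "chr9"),
               start = c(44355801, 112950759, 32578775, 47582292, 25160853, 129250000),
               stringsAsFactors = FALSE),
    aliases = c(NR2A1 = "HNF4A", OMC = "POMC"))
}

grid_catalog <- function(n = 10, per_chrom = 2, spacing = 5e6) {
  # n genes laid deterministically over chromosomes, no aliases
  chrom <- paste0("chr", rep(seq_len(ceiling(n / per_chrom)), each = per_chrom))[1:n]
  gene_catalog(data.frame(symbol = sprintf("G%03d", 1:n),
                          chromosome = chrom,
                          start = rep(seq_len(per_chrom) - 1, length.out = n) * spacing,
                          stringsAsFactors = FALSE))
}

# demo pipeline configuration scaled for test runs
small_config <- function(out_dir, seed = 1) {
  cfg <- default_config(out_dir = out_dir, seed = seed)
  cfg$simulate$n_genes <- 80L
  cfg$simulate$n_articles <- 120L
  cfg$simulate$n_frequent <- 4L
  cfg$simulate$n_infrequent <- 6L
  cfg$simulate$datasets <- data.frame(
    dataset_id = c("DS_A1", "DS_A2", "DS_B1"),
    platform_id = c("PA", "PA", "PB"),
    n_case = c(8L, 8L, 8L), n_control = c(8L, 8L, 8L),
    stringsAsFactors = FALSE)
  cfg$simulate$n_terms <- 20L
  cfg$thresholds$n_trees <- 60L
  cfg
}

small_feature_table <- function(n_per_class = 10, n_markers = 6, sep_marker = NULL,
                                sep = 4, seed = 1, group = "A") {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_markers), n, n_markers,
              dimnames = list(NULL, sprintf("M%02d", 1:n_markers)))
  y <- rep(c("case", "control"), each = n_per_class)
  if (!is.null(sep_marker)) X[y == "case", sep_marker] <- X[y == "case", sep_marker] + sep
  feature_table(group, X, y,
                setNames(sprintf("GENE%02d", 1:n_markers), colnames(X)))
}
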