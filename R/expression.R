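# Synthetic case/control expression datasets with planted structure.

#' Expression dataset container
#'
#' Holds one case/control expression dataset: a markers x samples matrix, a
#' marker-to-gene map, per-sample class labels, and (for synthetic data) the
#' planted ground truth used by recovery tests.
#'
#' @param dataset_id,platform_id identifiers; datasets sharing a
#'   `platform_id` share marker codes and can be column-combined.
#' @param matrix numeric markers x samples matrix with marker rownames and
#'   sample colnames.
#' @param marker_to_gene named character vector, marker code -> gene symbol.
#' @param labels character/factor vector of per-sample classes
#'   (`"case"`/`"control"`).
#' @param truth list with optional elements `deg` (named numeric: symbol ->
#'   signed planted effect), `corr_blocks` (list of character vectors),
#'   `biomarkers` (character vector of marker codes).
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(dataset_id, platform_id, matrix, marker_to_gene,
                               labels, truth = list()) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!all(is.finite(matrix))) stop_arg("expression values must be finite")
  labels <- as.character(labels)
  if (length(labels) != ncol(matrix))
    stop_arg("labels length (%d) must equal sample count (%d)",
             length(labels), ncol(matrix))
  if (!all(labels %in% c("case", "control")) || length(unique(labels)) < 2)
    stop_arg("labels must contain both 'case' and 'control'")
  if (is.null(rownames(matrix))) stop_arg("matrix must have marker rownames")
  if (!all(rownames(matrix) %in% names(marker_to_gene)))
    stop_arg("every marker row must appear in marker_to_gene")
  structure(list(dataset_id = dataset_id, platform_id = platform_id,
                 matrix = matrix,
                 marker_to_gene = marker_to_gene[rownames(matrix)],
                 labels = labels, truth = truth),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s [%s]: %d markers x %d samples (%d case / %d control)\n",
              x$dataset_id, x$platform_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$labels == "case"), sum(x$labels == "control")))
  invisible(x)
}

#' Simulate case/control expression datasets with planted truth
#'
#' Generates one dataset per row of `design` on a log2-like intensity scale
#' (Gaussian noise around per-gene baselines) or, with `scale = "counts"`, as
#' negative-binomial counts (used to exercise TMM normalization). Planted
#' structure, identical across datasets:
#'
#' * **Differential expression** — a fraction `de_fraction` of genes get a
#'   case-minus-control mean shift of `effect_size` (alternating sign),
#'   applied before noise, consistent in sign across datasets.
#' * **Correlation blocks** — each `corr_block_spec` entry `(size, r)` plants
#'   a gene block sharing a latent factor with loading `sqrt(r)`, so expected
#'   pairwise within-block correlation is near `r`.
#' * **Biomarkers** — `n_biomarkers` genes each get one marker per platform
#'   with an extra case shift of `biomarker_effect * noise_sd`, making that
#'   marker strongly class-discriminative.
#'
#' Genes can be measured by 1-2 markers (platform-specific codes); markers of
#' one gene share the gene-level signal plus marker noise.
#'
#' @param catalog a [gene_catalog()].
#' @param design data.frame with columns `dataset_id`, `platform_id`,
#'   `n_case`, `n_control` (each class >= 2).
#' @param de_fraction fraction of genes planted as DEGs, in `[0, 1]`.
#' @param effect_size planted case-control mean shift (expression units).
#' @param noise_sd per-sample Gaussian noise SD (> 0).
#' @param corr_block_spec list of `c(size, r)` pairs.
#' @param n_biomarkers,biomarker_effect planted discriminative markers.
#' @param markers_per_gene integer range, markers measured per gene.
#' @param baseline_mean,baseline_sd per-gene baseline distribution.
#' @param marker_noise_sd extra marker-level noise SD.
#' @param scale `"log"` (default) or `"counts"` (negative binomial;
#'   correlation blocks are not supported on the count scale).
#' @param seed integer seed.
#' @return list of [expression_dataset()] objects, with an attribute
#'   `"truth"` carrying the shared planted truth.
#' @export
generate_expression <- function(catalog, design, de_fraction = 0.05,
                                effect_size = 2.5, noise_sd = 1,
                                corr_block_spec = list(),
                                n_biomarkers = 0L, biomarker_effect = 2.5,
                                markers_per_gene = c(1L, 2L),
                                baseline_mean = 7, baseline_sd = 1,
                                marker_noise_sd = 0.25,
                                scale = c("log", "counts"), seed = 1L) {
  stopifnot(inherits(catalog, "gene_catalog"), is.data.frame(design),
            all(c("dataset_id", "platform_id", "n_case", "n_control") %in% names(design)))
  scale <- match.arg(scale)
  de_fraction <- check_prob(de_fraction, "de_fraction")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop_arg("`noise_sd` must be > 0")
  if (any(design$n_case < 2) || any(design$n_control < 2))
    stop_arg("each dataset needs >= 2 samples per class")
  genes <- catalog$genes$symbol
  n_genes <- length(genes)
  for (blk in corr_block_spec) {
    if (blk[[1]] > n_genes) stop_arg("correlation block size %d exceeds catalog size %d",
                                     blk[[1]], n_genes)
  }
  if (scale == "counts" && length(corr_block_spec))
    stop_arg("correlation blocks are only supported on the log scale")

  with_seed(seed, {
    # ---- shared planted truth -------------------------------------------
    n_de <- round(de_fraction * n_genes)
    de_genes <- if (n_de > 0) sample(genes, n_de) else character()
    de_sign <- if (n_de > 0) rep_len(c(1, -1), n_de) else numeric()
    truth_deg <- stats::setNames(de_sign * effect_size, de_genes)

    pool <- setdiff(genes, de_genes)
    blocks <- list()
    for (blk in corr_block_spec) {
      size <- as.integer(blk[[1]])
      src <- if (length(pool) >= size) pool else genes
      members <- sample(src, size)
      pool <- setdiff(pool, members)
      blocks[[length(blocks) + 1L]] <- list(genes = members, r = as.numeric(blk[[2]]))
    }
    bm_pool <- if (length(pool) >= n_biomarkers) pool else genes
    bm_genes <- if (n_biomarkers > 0) sample(bm_pool, n_biomarkers) else character()

    baseline <- stats::setNames(stats::rnorm(n_genes, baseline_mean, baseline_sd), genes)

    # ---- platform marker maps -------------------------------------------
    platforms <- unique(design$platform_id)
    marker_maps <- list(); bm_markers <- list()
    for (pf in platforms) {
      mk_choices <- seq(markers_per_gene[1], markers_per_gene[length(markers_per_gene)])
      n_mk <- mk_choices[sample.int(length(mk_choices), n_genes, replace = TRUE)]
      code <- unlist(lapply(seq_len(n_genes), function(i)
        sprintf("%s_%04d_%02d", pf, i, seq_len(n_mk[i]))), use.names = FALSE)
      gene_of <- rep(genes, n_mk)
      # planted biomarker = first marker of each biomarker gene on this platform
      bm <- vapply(bm_genes, function(g) code[which(gene_of == g)[1]], character(1))
      marker_maps[[pf]] <- stats::setNames(gene_of, code)
      bm_markers[[pf]] <- unname(bm)
    }

    truth <- list(deg = truth_deg,
                  corr_blocks = lapply(blocks, `[[`, "genes"),
                  biomarkers = bm_markers)

    # ---- per-dataset matrices -------------------------------------------
    datasets <- lapply(seq_len(nrow(design)), function(d) {
      row <- design[d, ]
      pf <- row$platform_id
      m2g <- marker_maps[[pf]]
      n_case <- as.integer(row$n_case); n_ctrl <- as.integer(row$n_control)
      n <- n_case + n_ctrl
      labels <- c(rep("case", n_case), rep("control", n_ctrl))
      is_case <- labels == "case"
      sample_ids <- sprintf("%s_S%03d", row$dataset_id, seq_len(n))

      if (scale == "log") {
        gene_sig <- matrix(stats::rnorm(n_genes * n, 0, noise_sd), n_genes, n,
                           dimnames = list(genes, sample_ids))
        for (blk in blocks) { # latent-factor blocks: x = sqrt(r) f + sqrt(1-r) e
          f <- stats::rnorm(n)
          lam <- sqrt(blk$r)
          e <- matrix(stats::rnorm(length(blk$genes) * n), length(blk$genes), n)
          gene_sig[blk$genes, ] <- noise_sd * (lam * rep(f, each = length(blk$genes)) +
                                                 sqrt(1 - blk$r) * e)
        }
        gene_sig <- gene_sig + baseline[genes]
        if (length(truth_deg))
          gene_sig[names(truth_deg), is_case] <- gene_sig[names(truth_deg), is_case] +
            unname(truth_deg)
        mat <- gene_sig[unname(m2g), , drop = FALSE] +
          matrix(stats::rnorm(length(m2g) * n, 0, marker_noise_sd), length(m2g), n)
        rownames(mat) <- names(m2g)
        if (length(bm_markers[[pf]]))
          mat[bm_markers[[pf]], is_case] <- mat[bm_markers[[pf]], is_case] +
            biomarker_effect * noise_sd
      } else {
        mu_gene <- 2^baseline  # lognormal-ish count means
        lib <- exp(stats::rnorm(n, 0, 0.25))
        mu <- outer(mu_gene[unname(m2g)], lib)
        if (length(truth_deg)) {
          shift <- 2^unname(truth_deg)
          de_rows <- m2g %in% names(truth_deg)
          mu[de_rows, is_case] <- mu[de_rows, is_case] *
            shift[match(m2g[de_rows], names(truth_deg))]
        }
        mat <- matrix(stats::rnbinom(length(mu), mu = mu, size = 10),
                      nrow(mu), ncol(mu),
                      dimnames = list(names(m2g), sample_ids))
        mat <- mat + 0  # integer -> double
      }
      expression_dataset(row$dataset_id, pf, mat, m2g, labels,
                         truth = c(truth, list(platform = pf)))
    })
    names(datasets) <- design$dataset_id
    attr(datasets, "truth") <- truth
    datasets
  })
}

#' Write / read an expression dataset as series-matrix-style TSV
#'
#' Layout: two metadata header lines (`!Sample_id`, `!Sample_class`) followed
#' by a markers x samples table with the marker code in the first column.
#'
#' @param ds an [expression_dataset()].
#' @param path file path for the matrix; the marker-to-gene map is written to
#'   `<path>.markers.tsv`.
#' @return the path (writer); an [expression_dataset()] (reader).
#' @export
write_expression <- function(ds, path) {
  stopifnot(inherits(ds, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("!Sample_id", colnames(ds$matrix)), collapse = "\t"),
               paste(c("!Sample_class", ds$labels), collapse = "\t"),
               paste(c("ID_REF", colnames(ds$matrix)), collapse = "\t")), con)
  utils::write.table(data.frame(ID_REF = rownames(ds$matrix), ds$matrix,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_tsv(data.frame(marker = names(ds$marker_to_gene),
                       gene = unname(ds$marker_to_gene)),
            paste0(path, ".markers.tsv"))
  invisible(path)
}

#' @rdname write_expression
#' @param dataset_id,platform_id identifiers to attach on read.
#' @export
read_expression <- function(path, dataset_id = basename(path), platform_id = "unknown") {
  lines <- readLines(path, n = 2L)
  if (!startsWith(lines[1], "!Sample_id") || !startsWith(lines[2], "!Sample_class"))
    stop_arg("%s is not a series-matrix-style file (missing !Sample_* headers)", path)
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  mk <- read_tsv(paste0(path, ".markers.tsv"))
  expression_dataset(dataset_id, platform_id, mat,
                     stats::setNames(mk$gene, mk$marker), labels)
}
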