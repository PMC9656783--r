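# TMM (trimmed mean of M-values) per-sample scale factors.

#' TMM per-sample scale factors
#'
#' Implements the trimmed-mean-of-M-values recipe: the reference sample is
#' the one whose library-size-scaled upper quartile is closest to the mean
#' upper quartile; for every sample, M (log2 expression ratio vs the
#' reference, library-size normalized) and A (mean log2 abundance) are
#' computed over markers with nonzero counts in both samples; M is doubly
#' trimmed (`trim_m` of the M distribution, `trim_a` of the A distribution,
#' both sides each); the composition factor is `2^(precision-weighted mean
#' of the surviving M)`, with inverse asymptotic (delta-method) variances as
#' weights.
#'
#' The returned value per sample is the *scale* factor actually used for
#' normalization — composition factor times library size — rescaled so the
#' factors have geometric mean 1. Dividing a sample's column by its factor
#' equalizes effective library sizes across samples; a sample that is a
#' uniform 2-fold copy of another therefore gets twice its factor.
#'
#' @param counts non-negative markers x samples matrix; no all-zero sample.
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of positive factors, geometric mean 1, with
#'   attributes `ref_sample` (reference column) and `composition` (the
#'   library-size-free TMM composition factors, also geometric mean 1).
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_arg("`counts` must be a numeric matrix")
  if (any(counts < 0) || anyNA(counts)) stop_arg("counts must be non-negative and finite")
  lib <- colSums(counts)
  if (any(lib == 0)) stop_arg("degenerate input: sample(s) with all-zero counts")
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- paste0("S", seq_len(n))

  # reference: upper quartile (scaled by library size) closest to the mean
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  comp <- vapply(seq_len(n), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  scale <- comp * lib
  scale <- scale / exp(mean(log(scale)))
  structure(stats::setNames(scale, colnames(counts)),
            ref_sample = colnames(counts)[ref],
            composition = comp / exp(mean(log(comp))))
}

# TMM composition factor of one sample against the reference
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0            # zeros in either sample excluded
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  w <- 1 / v                           # precision (inverse delta-method variance)
  if (max(abs(M)) < 1e-6) return(1)    # samples already proportional
  m <- length(M)
  lo_m <- floor(m * trim_m) + 1; hi_m <- m + 1 - lo_m
  lo_a <- floor(m * trim_a) + 1; hi_a <- m + 1 - lo_a
  rM <- rank(M); rA <- rank(A)
  kept <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(kept) || sum(w[kept]) == 0) return(1)
  2^(sum(M[kept] * w[kept]) / sum(w[kept]))
}

#' Apply TMM scale factors to a matrix
#'
#' Divides each sample column by its factor.
#'
#' @param mat markers x samples matrix.
#' @param factors output of [tmm_factors()] (or any per-sample factor).
#' @return normalized matrix of the same shape.
#' @export
normalize_tmm <- function(mat, factors = tmm_factors(mat)) {
  stopifnot(ncol(mat) == length(factors))
  sweep(mat, 2, as.numeric(factors), "/")
}
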