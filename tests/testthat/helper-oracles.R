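# Independent oracle implementations used to cross-check the package.
# These deliberately use different code paths (regex scans, explicit loops,
# exhaustive enumeration) than the implementations they validate.

# brute-force per-(gene, article) regex scan of raw text; token boundaries
# are non-alphanumeric-non-hyphen characters or string ends
oracle_scan_corpus <- function(corpus, catalog, blacklist = character()) {
  articles <- if (inherits(corpus, "synthetic_corpus")) corpus$articles else corpus
  dict <- c(stats::setNames(catalog$genes$symbol, catalog$genes$symbol),
            catalog$aliases)
  dict <- dict[!(names(dict) %in% blacklist)]
  per_gene <- list()
  for (tok_i in seq_along(dict)) {
    tok <- names(dict)[tok_i]
    sym <- unname(dict[tok_i])
    pat <- paste0("(^|[^[:alnum:]-])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", tok),
                  "([^[:alnum:]-]|$)")
    hit <- grepl(pat, articles$text)
    if (any(hit)) {
      per_gene[[sym]] <- sort(unique(c(per_gene[[sym]],
                                       articles$article_id[hit])))
    }
  }
  per_gene[order(names(per_gene))]
}

# DerSimonian-Laird pooling written as an explicit step list
oracle_dl <- function(g, v) {
  k <- length(g)
  w_fixed <- 1 / v
  mu_fixed <- sum(w_fixed * g) / sum(w_fixed)
  Q <- sum(w_fixed * (g - mu_fixed)^2)
  C <- sum(w_fixed) - sum(w_fixed^2) / sum(w_fixed)
  tau2 <- if (k > 1 && C > 0) max(0, (Q - (k - 1)) / C) else 0
  w_re <- 1 / (v + tau2)
  mu <- sum(w_re * g) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  list(pooled = mu, tau2 = tau2, z = mu / se,
       p = 2 * (1 - pnorm(abs(mu / se))))
}

# step-by-step TMM scale factors (explicit loops, no vectorized shortcuts)
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) lib[j] <- sum(counts[, j])
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    uq[j] <- quantile(counts[, j], 0.75) / lib[j]
  }
  ref <- which.min(abs(uq - mean(uq)))
  comp <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- c(); W <- c(); A <- c()
    for (i in seq_len(nrow(counts))) {
      o <- counts[i, j]; r <- counts[i, ref]
      if (o > 0 && r > 0) {
        M <- c(M, log2((o / lib[j]) / (r / lib[ref])))
        A <- c(A, 0.5 * log2((o / lib[j]) * (r / lib[ref])))
        W <- c(W, 1 / ((lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)))
      }
    }
    if (!length(M) || max(abs(M)) < 1e-6) { comp[j] <- 1; next }
    m <- length(M)
    lo_m <- floor(m * trim_m) + 1; hi_m <- m + 1 - lo_m
    lo_a <- floor(m * trim_a) + 1; hi_a <- m + 1 - lo_a
    rm_ <- rank(M); ra_ <- rank(A)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
    comp[j] <- if (any(keep)) 2^(sum(M[keep] * W[keep]) / sum(W[keep])) else 1
  }
  s <- comp * lib
  s / exp(mean(log(s)))
}

# hypergeometric upper tail by exhaustive enumeration of list subsets
oracle_hypergeom_enum <- function(overlap, list_size, term_size, background_size) {
  bg <- seq_len(background_size)
  term <- seq_len(term_size)
  subsets <- combn(bg, list_size)
  ov <- apply(subsets, 2, function(s) length(intersect(s, term)))
  mean(ov >= overlap)
}

# exhaustive all-pairs network recomputation via cor.test
oracle_network_edges <- function(expr, r_min, p_max) {
  genes <- rownames(expr)
  rows <- list()
  for (i in seq_len(nrow(expr) - 1)) {
    for (j in (i + 1):nrow(expr)) {
      x <- expr[i, ]; y <- expr[j, ]
      if (sd(x) == 0 || sd(y) == 0) next
      ct <- cor.test(x, y)
      r <- unname(ct$estimate)
      if (abs(r) >= r_min && ct$p.value <= p_max) {
        a <- genes[i]; b <- genes[j]
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = a, gene_b = b, r = r, p = ct$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# construct two vectors with an exact sample correlation r
vectors_with_r <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))              # orthogonal to x empirically
  x <- as.numeric(scale(x)); e <- as.numeric(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
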