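# Shared fixtures and small independent oracles used across test files.

# Richardson Utah chill-unit weighting, transcribed from the published band
# table (one-decimal resolution). Independent of the package implementation.
richardson_oracle <- function(t) {
  vapply(t, function(x) {
    if (x <= 1.4) 0
    else if (x <= 2.4) 0.5
    else if (x <= 9.1) 1.0
    else if (x <= 12.4) 0.5
    else if (x <= 15.9) 0
    else if (x <= 18.0) -0.5
    else -1.0
  }, numeric(1))
}

# Brute-force TMM oracle: literal trimmed-mean-of-M computation, reference
# chosen by upper quartile closest to the mean, factors rescaled to unit
# geometric mean. Written from the definition, separately from the package.
tmm_oracle <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(j) {
    p1 <- counts[, j] / lib[j]
    p2 <- counts[, ref] / lib[ref]
    ok <- counts[, j] > 0 & counts[, ref] > 0
    m <- log2(p1[ok] / p2[ok])
    a <- (log2(p1[ok]) + log2(p2[ok])) / 2
    if (max(abs(m)) < 1e-10) return(1)
    n <- length(m)
    keep_m <- rank(m) >= floor(n * trim_m) + 1 & rank(m) <= n - floor(n * trim_m)
    keep_a <- rank(a) >= floor(n * trim_a) + 1 & rank(a) <= n - floor(n * trim_a)
    if (!any(keep_m & keep_a)) return(1)
    2^mean(m[keep_m & keep_a])
  })
  f / exp(mean(log(f)))
}

# Literal enumeration of the reduced-graph rule: union of per-gene top-k
# partners (signed r, lexicographic tie-break), r >= r_min, isolates dropped.
topk_graph_oracle <- function(corr, k = 5, r_min = 0.75) {
  genes <- rownames(corr)
  edges <- character(0)
  for (g in genes) {
    others <- setdiff(genes, g)
    r <- corr[g, others]
    ord <- order(-r, others)
    for (p in others[ord][seq_len(min(k, length(others)))]) {
      e <- paste(sort(c(g, p)), collapse = "|")
      if (corr[g, p] >= r_min) edges <- union(edges, e)
    }
  }
  sort(edges)
}

# Small deterministic expression toy: 6 genes x 8 samples with two clearly
# correlated pairs and independent leftovers.
toy_expr <- function() {
  set.seed(99)
  base <- matrix(rnorm(6 * 8), 6, 8,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  base[2, ] <- base[1, ] + rnorm(8, sd = 0.01)
  base[4, ] <- -base[3, ] + rnorm(8, sd = 0.01)
  base
}

edge_keys <- function(graph) {
  sort(paste(graph$edges$gene_a, graph$edges$gene_b, sep = "|"))
}
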