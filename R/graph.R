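#' Pairwise Pearson correlation of a gene subset
#'
#' @param expr_subset Expression matrix, genes x samples (>= 2 genes,
#'   >= 3 samples). Constant genes are rejected by name.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(expr_subset) {
  assert_matrix_like(expr_subset)
  if (nrow(expr_subset) < 2) stop("need >= 2 genes")
  if (ncol(expr_subset) < 3) stop("need >= 3 samples")
  sds <- apply(expr_subset, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant gene '%s' has undefined correlation",
                 rownames(expr_subset)[sds == 0][1]))
  }
  r <- stats::cor(t(expr_subset))
  diag(r) <- 1
  r
}

#' Reduced top-k thresholded co-expression graph
#'
#' Implements the reduced-network rule: for every gene keep its `k` most
#' highly correlated partners (signed r descending; ties broken by
#' lexicographic partner id), take the union of these candidate edges over
#' genes, discard edges with r below `r_min` (boundary kept), and drop
#' isolated nodes. Because the rule is a union rather than a mutual
#' requirement, hub nodes can exceed degree k.
#'
#' @param corr Symmetric correlation matrix from [pairwise_correlation()].
#' @param k Partners retained per gene (default 5).
#' @param r_min Minimum retained correlation (default 0.75).
#' @param rank_abs Rank partners by |r| instead of signed r (default FALSE,
#'   the literal "most highly correlated" reading).
#' @return List of class `"coexpr_graph"`: `edges` (data.frame gene_a,
#'   gene_b, r; gene_a < gene_b; sorted), `nodes` (data.frame gene, degree),
#'   `k`, `r_min`.
#' @export
build_topk_graph <- function(corr, k = 5, r_min = 0.75, rank_abs = FALSE) {
  if (k < 1) stop("`k` must be >= 1")
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  genes <- rownames(corr)
  n <- length(genes)
  cand <- character(0)
  for (i in seq_len(n)) {
    r_i <- corr[i, -i]
    key <- if (rank_abs) abs(r_i) else r_i
    ord <- order(-key, names(r_i))
    top <- names(r_i)[ord][seq_len(min(k, n - 1))]
    pair <- ifelse(genes[i] < top,
                   paste(genes[i], top, sep = "\r"),
                   paste(top, genes[i], sep = "\r"))
    cand <- c(cand, pair)
  }
  cand <- unique(cand)
  parts <- strsplit(cand, "\r", fixed = TRUE)
  ga <- vapply(parts, `[`, "", 1)
  gb <- vapply(parts, `[`, "", 2)
  rv <- corr[cbind(ga, gb)]
  keep <- if (rank_abs) abs(rv) >= r_min else rv >= r_min
  edges <- data.frame(gene_a = ga[keep], gene_b = gb[keep], r = rv[keep])
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  deg <- table(factor(c(edges$gene_a, edges$gene_b), levels = genes))
  nodes <- data.frame(gene = genes, degree = as.integer(deg))
  nodes <- nodes[nodes$degree > 0, , drop = FALSE]  # isolated nodes excluded
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes, k = k, r_min = r_min),
            class = "coexpr_graph")
}

#' Degree bin label per node
#'
#' Bins match the presentation convention for node sizes: 1, 2-4, 5-6, 7-9
#' and >=10 connections (degree-1 nodes get their own bin below the smallest
#' published size class).
#'
#' @param graph A `"coexpr_graph"` from [build_topk_graph()].
#' @return data.frame `gene`, `degree`, `bin`.
#' @export
degree_bins <- function(graph) {
  stopifnot(inherits(graph, "coexpr_graph"))
  d <- graph$nodes$degree
  bin <- cut(d, breaks = c(0, 1, 4, 6, 9, Inf),
             labels = c("1", "2-4", "5-6", "7-9", ">=10"))
  data.frame(gene = graph$nodes$gene, degree = d, bin = as.character(bin))
}
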