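#' TMM normalization factors
#'
#' Trimmed mean of M-values (TMM) between-sample normalization factors for a
#' count matrix. The reference sample is the one whose upper quartile (of
#' counts-per-million) is closest to the mean upper quartile. For each sample,
#' gene-wise log2 ratios to the reference (M) and average log2 abundances (A)
#' are computed on library-size-scaled counts; genes in the extreme
#' `trim_m` tails of M and `trim_a` tails of A are discarded and the factor
#' is 2 to the unweighted mean of the remaining M values. Factors are rescaled
#' so their geometric mean is 1.
#'
#' @param counts Integer/numeric matrix, genes x samples, >= 2 samples.
#' @param trim_m Two-sided trim fraction on M values (default 0.3).
#' @param trim_a Two-sided trim fraction on A values (default 0.05).
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  assert_matrix_like(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop(sprintf("sample '%s' has all-zero counts", colnames(counts)[lib == 0][1]))
  }
  uq <- apply(counts, 2, function(x) stats::quantile(x[x > 0] / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# Unweighted trimmed mean of M for one sample against the reference.
tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  m <- log2(p_obs[keep] / p_ref[keep])
  a <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  if (max(abs(m)) < 1e-10) return(1)  # identical composition
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  2^mean(m[keep2])
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' @param counts Count matrix, genes x samples.
#' @param factors Per-sample TMM factors from [tmm_factors()].
#' @param pseudocount Added on the CPM scale before log2 (default 1).
#' @return Matrix of log2(CPM + pseudocount) values.
#' @export
normalize_log_cpm <- function(counts, factors, pseudocount = 1) {
  assert_matrix_like(counts)
  if (!setequal(names(factors), colnames(counts))) {
    stop("`factors` sample names do not match `counts` columns")
  }
  eff <- colSums(counts) * factors[colnames(counts)]
  log2(sweep(counts, 2, eff, `/`) * 1e6 + pseudocount)
}

#' Remove batch-associated residual variation
#'
#' ANOVA-decomposition batch correction: per-gene group (e.g. organ x
#' timepoint) means are fitted and preserved; principal components of the
#' residual matrix whose sample scores correlate with the batch indicator
#' beyond `cor_threshold` are subtracted. A single batch, or a batch design
#' perfectly confounded with the groups, is a warning + no-op.
#'
#' @param matrix_log Normalized log2 expression, genes x samples.
#' @param batch_labels Batch per sample.
#' @param group_labels Biological group per sample (kept intact).
#' @param n_components Number of leading residual PCs examined (default 2).
#' @param cor_threshold Absolute correlation with the batch indicator above
#'   which a component is considered batch-driven (default 0.7).
#' @return Corrected matrix, same dimensions.
#' @export
correct_batch <- function(matrix_log, batch_labels, group_labels,
                          n_components = 2, cor_threshold = 0.7) {
  assert_matrix_like(matrix_log)
  batch_labels <- as.character(batch_labels)
  group_labels <- as.character(group_labels)
  stopifnot(length(batch_labels) == ncol(matrix_log),
            length(group_labels) == ncol(matrix_log))
  if (length(unique(batch_labels)) < 2) {
    return(matrix_log)
  }
  confounded <- all(vapply(split(batch_labels, group_labels),
                           function(b) length(unique(b)) == 1, logical(1)))
  if (confounded) {
    warning("batch is perfectly confounded with the groups; no correction applied")
    return(matrix_log)
  }
  group_means <- row_group_means(matrix_log, group_labels)
  fitted <- group_means[, match(group_labels, unique(group_labels)),
                        drop = FALSE]
  resid <- matrix_log - fitted
  # PCA with samples as observations; batch lives in the sample scores
  sv <- svd(t(resid - rowMeans(resid)))
  batch_num <- as.numeric(factor(batch_labels))
  k <- min(n_components, length(sv$d))
  for (comp in seq_len(k)) {
    score <- sv$u[, comp] * sv$d[comp]
    if (stats::sd(score) == 0) next
    if (abs(stats::cor(score, batch_num)) > cor_threshold) {
      resid <- resid - tcrossprod(sv$v[, comp], score)
    }
  }
  out <- fitted + resid
  dimnames(out) <- dimnames(matrix_log)
  out
}

#' Per-gene differential expression across timepoints
#'
#' One-way F-test per gene across timepoint groups on log2 expression (a
#' documented surrogate for the original study pipeline's DE engine), with
#' per-contrast log2 fold changes against the first timepoint and
#' Benjamini-Hochberg adjustment across genes.
#'
#' @param matrix_log Normalized log2 expression, genes x samples.
#' @param timepoint Timepoint factor per sample (first level = reference).
#' @return data.frame with columns `gene_id`, `contrast`, `log2fc`,
#'   `p_value`, `fdr` (p and fdr are gene-level, repeated per contrast).
#' @export
test_de <- function(matrix_log, timepoint) {
  assert_matrix_like(matrix_log)
  tp <- factor(timepoint)
  stopifnot(length(tp) == ncol(matrix_log))
  tab <- table(tp)
  if (any(tab < 2)) {
    drop <- names(tab)[tab < 2]
    warning("dropping timepoint(s) with a single replicate: ",
            paste(drop, collapse = ", "))
    keep <- !(tp %in% drop)
    matrix_log <- matrix_log[, keep, drop = FALSE]
    tp <- droplevels(tp[keep])
  }
  if (nlevels(tp) < 2) stop("need >= 2 timepoints with >= 2 replicates")
  groups <- levels(tp)
  n <- ncol(matrix_log)
  k <- length(groups)
  gm <- row_group_means(matrix_log, tp, groups)
  grand <- rowMeans(matrix_log)
  n_g <- as.numeric(table(tp)[groups])
  ss_between <- rowSums(sweep((gm - grand)^2, 2, n_g, `*`))
  fitted <- gm[, as.integer(tp), drop = FALSE]
  ss_within <- rowSums((matrix_log - fitted)^2)
  df1 <- k - 1
  df2 <- n - k
  fstat <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  p[ss_within < 1e-12 & ss_between < 1e-12] <- 1  # flat genes: no signal
  fdr <- bh_adjust(p)
  ref <- groups[1]
  out <- do.call(rbind, lapply(groups[-1], function(g) {
    data.frame(
      gene_id = rownames(matrix_log),
      contrast = paste0(g, "_vs_", ref),
      log2fc = gm[, g] - gm[, ref],
      p_value = p,
      fdr = fdr,
      row.names = NULL
    )
  }))
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; NA rejected.
#' @return Adjusted p-values (FDR).
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values)) stop("NA p-values are not allowed")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Filter DEG records by fold change and FDR
#'
#' A gene survives if its maximum absolute log2 fold change across contrasts
#' is at least `log2(fc_min)` (boundary inclusive) and its minimum FDR is at
#' most `fdr_max`.
#'
#' @param records data.frame from [test_de()].
#' @param fc_min Fold-change threshold on the natural scale (>= 1).
#' @param fdr_max FDR ceiling (0.05 for the global DEG set, 0.01 for the
#'   more stringent network input set).
#' @return Character vector of surviving gene ids (sorted).
#' @export
filter_deg <- function(records, fc_min = 1.4, fdr_max = 0.05) {
  if (fc_min < 1) stop("`fc_min` must be >= 1")
  max_fc <- tapply(abs(records$log2fc), records$gene_id, max)
  min_fdr <- tapply(records$fdr, records$gene_id, min)
  genes <- names(max_fc)
  sort(genes[max_fc >= log2(fc_min) & min_fdr[genes] <= fdr_max])
}

#' Two-set Venn partition
#'
#' @param setA,setB Character vectors (de-duplicated internally).
#' @return List with `shared`, `unique_a`, `unique_b` counts and the
#'   corresponding gene-id vectors.
#' @export
venn_partition <- function(setA, setB) {
  a <- unique(setA)
  b <- unique(setB)
  list(
    shared = length(intersect(a, b)),
    unique_a = length(setdiff(a, b)),
    unique_b = length(setdiff(b, a)),
    shared_ids = sort(intersect(a, b)),
    unique_a_ids = sort(setdiff(a, b)),
    unique_b_ids = sort(setdiff(b, a))
  )
}
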