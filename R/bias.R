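#' Per-gene organ-bias linear model
#'
#' Fits `expression ~ Condition + Timepoint` by least squares for every gene,
#' where Condition contrasts the two bud organs and categorical Timepoint
#' absorbs temporal variation. The reported coefficient follows the
#' flower-minus-vegetative sign convention: positive values mean higher
#' expression in flower buds. All genes share one design matrix, so the fit
#' is done through a single QR decomposition.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param condition Organ per sample ("flower"/"vegetative").
#' @param timepoint Timepoint per sample (coerced to factor).
#' @return data.frame with `gene_id`, `coef_condition`, `p_condition`.
#' @export
fit_condition_model <- function(expr, condition, timepoint) {
  assert_matrix_like(expr)
  condition <- as.character(condition)
  stopifnot(length(condition) == ncol(expr),
            length(timepoint) == ncol(expr))
  if (length(unique(condition)) != 2) stop("need exactly two organ levels")
  tp <- factor(timepoint)
  if (nlevels(tp) < 2) stop("need >= 2 timepoints")
  # flower minus vegetative sign convention
  cond <- factor(condition, levels = c("vegetative", "flower"))
  if (anyNA(cond)) cond <- factor(condition)  # other labels: first level = ref
  design <- stats::model.matrix(~ cond + tp)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient design: organ is confounded with timepoint")
  }
  coefs <- t(qr.coef(qrd, t(expr)))
  fitted <- t(qr.fitted(qrd, t(expr)))
  df <- ncol(expr) - ncol(design)
  rss <- rowSums((expr - fitted)^2)
  sigma2 <- rss / df
  xtx_inv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tstat <- coefs[, 2] / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[se == 0] <- ifelse(abs(coefs[se == 0, 2]) < 1e-12, 1, 0)
  data.frame(
    gene_id = rownames(expr),
    coef_condition = unname(coefs[, 2]),
    p_condition = unname(p),
    row.names = NULL
  )
}

#' Classify genes as flower-biased, vegetative-biased or balanced
#'
#' A gene is flower-biased when its condition coefficient reaches
#' `+coef_min` (boundary inclusive) with BH-adjusted p below `alpha`,
#' vegetative-biased when it falls below `-coef_min` with the same
#' significance gate, and balanced otherwise.
#'
#' @param coef Condition coefficients (flower minus vegetative, log2 scale).
#' @param p Raw p-values of the coefficient; BH-adjusted internally.
#' @param coef_min Minimum absolute coefficient (default `log2(1.5)`).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Character vector in \{"flower", "vegetative", "balanced"\}.
#' @export
classify_bias <- function(coef, p, coef_min = log2(1.5), alpha = 0.05) {
  stopifnot(length(coef) == length(p))
  fdr <- bh_adjust(p)
  out <- rep("balanced", length(coef))
  out[coef >= coef_min & fdr < alpha] <- "flower"
  out[coef <= -coef_min & fdr < alpha] <- "vegetative"
  out
}

#' Organ-specificity call from expression presence
#'
#' A gene is organ-specific when it is expressed (log2 value above
#' `min_expr`, i.e. CPM >= 1 by default) in at least `min_samples` samples of
#' exactly one organ; otherwise it is shared (or unexpressed).
#'
#' @param expr Log2(CPM + 1) matrix, genes x samples.
#' @param organ Organ label per sample.
#' @param min_expr Expression floor on the log2 scale (default 1, i.e.
#'   CPM >= 1).
#' @param min_samples Minimum expressed samples per organ (default 2).
#' @return Character vector per gene in \{"shared", "flower_specific",
#'   "vegetative_specific", "unexpressed"\}.
#' @export
call_specificity <- function(expr, organ, min_expr = 1, min_samples = 2) {
  assert_matrix_like(expr)
  organ <- as.character(organ)
  present <- vapply(unique(organ), function(o) {
    rowSums(expr[, organ == o, drop = FALSE] >= min_expr) >= min_samples
  }, logical(nrow(expr)))
  colnames(present) <- unique(organ)
  out <- rep("unexpressed", nrow(expr))
  out[present[, "flower"] & present[, "vegetative"]] <- "shared"
  out[present[, "flower"] & !present[, "vegetative"]] <- "flower_specific"
  out[!present[, "flower"] & present[, "vegetative"]] <- "vegetative_specific"
  out
}

#' PCA over genes on shared-gene expression features
#'
#' Genes are the observations; features default to organ x timepoint mean
#' expression. Each gene's feature vector is first centered on its own mean
#' (so the components capture profile shape, not absolute expression level),
#' then a standard column-centered PCA is computed.
#'
#' @param features Numeric matrix, genes x features (e.g. from
#'   [group_mean_features()]).
#' @param row_center Remove each gene's mean before PCA (default TRUE).
#' @return List of class `"pca_model"`: `loadings`, `center` (column means),
#'   `row_center` flag, `scores` (training genes), `variance_explained` (%).
#' @export
pca_shared <- function(features, row_center = TRUE) {
  if (nrow(features) < 3 || ncol(features) < 3) {
    stop("need >= 3 genes and >= 3 features")
  }
  x <- as.matrix(features)
  if (row_center) x <- x - rowMeans(x)
  if (all(abs(x - mean(x)) < 1e-12)) stop("constant feature matrix")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  structure(list(
    loadings = pc$rotation,
    center = pc$center,
    row_center = row_center,
    scores = pc$x,
    variance_explained = 100 * pc$sdev^2 / sum(pc$sdev^2)
  ), class = "pca_model")
}

#' Project genes into an existing PCA space
#'
#' Applies the training transform (row centering if configured, stored
#' column centering, rotation) to new gene feature vectors. Projecting a
#' training gene reproduces its stored score.
#'
#' @param model A `"pca_model"` from [pca_shared()].
#' @param features Matrix, genes x features (same feature space).
#' @return Score matrix, genes x components.
#' @export
project_specific <- function(model, features) {
  stopifnot(inherits(model, "pca_model"))
  x <- as.matrix(features)
  if (ncol(x) != length(model$center)) {
    stop("feature dimension mismatch with the trained PCA space")
  }
  if (model$row_center) x <- x - rowMeans(x)
  x <- sweep(x, 2, model$center)
  x %*% model$loadings
}

#' Organ x timepoint mean-expression features for gene-space PCA
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param organ,timepoint Sample annotations.
#' @return Matrix, genes x (organ x timepoint) group means.
#' @export
group_mean_features <- function(expr, organ, timepoint) {
  assert_matrix_like(expr)
  grp <- interaction(organ, timepoint, drop = TRUE, lex.order = TRUE)
  row_group_means(expr, as.character(grp), levels(grp))
}

#' Correlation between PC1 scores and the organ-bias coefficient
#'
#' @param pc1_scores PC1 score per gene.
#' @param coef_conditions Condition coefficient per gene (same order).
#' @return Pearson r (signed, reported as-is).
#' @export
pc_bias_correlation <- function(pc1_scores, coef_conditions) {
  stopifnot(length(pc1_scores) == length(coef_conditions),
            length(pc1_scores) >= 3)
  if (stats::sd(pc1_scores) == 0 || stats::sd(coef_conditions) == 0) {
    stop("zero variance input")
  }
  stats::cor(pc1_scores, coef_conditions)
}
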