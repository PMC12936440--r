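#' Choose a soft-threshold power by the scale-free topology criterion
#'
#' For each candidate power the signed/unsigned adjacency is formed, gene
#' connectivity k is binned, and the fit of log10 p(k) against log10 k is
#' scored; the scale-free fit R^2 is the linear-model R^2 when the slope is
#' negative (else 0). The smallest power with fit >= `target_r2` is chosen;
#' with none qualifying, the conventional default 6 is used with a warning.
#'
#' @param expr Log2 expression matrix, genes x samples (>= 20 genes).
#' @param candidate_powers Powers examined (default 1:20).
#' @param target_r2 Required scale-free fit (default 0.8).
#' @param type Adjacency type, `"signed"` (default) or `"unsigned"`.
#' @param n_bins Connectivity histogram bins (default 10).
#' @return List: `power`, `fit_table` (power, r_squared, slope).
#' @export
soft_threshold_power <- function(expr, candidate_powers = 1:20,
                                 target_r2 = 0.8, type = c("signed", "unsigned"),
                                 n_bins = 10) {
  assert_matrix_like(expr)
  type <- match.arg(type)
  if (nrow(expr) < 20) stop("need >= 20 genes")
  if (any(apply(expr, 1, stats::sd) == 0)) {
    stop("constant genes present; remove them before thresholding")
  }
  r <- stats::cor(t(expr))
  if (anyNA(r)) stop("correlation matrix contains NA")
  base <- if (type == "unsigned") abs(r) else (1 + r) / 2
  fit <- do.call(rbind, lapply(candidate_powers, function(beta) {
    a <- base^beta
    diag(a) <- 0
    k <- rowSums(a)
    sf <- scale_free_fit(k, n_bins)
    data.frame(power = beta, r_squared = sf$r2, slope = sf$slope)
  }))
  ok <- fit$power[fit$r_squared >= target_r2 & fit$slope < 0]
  if (length(ok)) {
    power <- min(ok)
  } else {
    warning("no candidate power reached the scale-free fit target; using 6")
    power <- 6
  }
  list(power = power, fit_table = fit)
}

scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(list(r2 = 0, slope = 0))
  cuts <- cut(k, breaks = n_bins)
  pk <- tapply(k, cuts, length) / length(k)
  km <- tapply(k, cuts, mean)
  keep <- !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(list(r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(km[keep]))
  list(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}

#' Soft-thresholded adjacency and topological overlap
#'
#' Adjacency is `a_ij = |cor|^beta` (unsigned) or `((1+cor)/2)^beta`
#' (signed); the topological overlap similarity is
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with unit
#' diagonal.
#'
#' @param expr Log2 expression matrix, genes x samples.
#' @param soft_power Soft-threshold exponent beta (>= 1).
#' @param type `"signed"` (default) or `"unsigned"`.
#' @return List of class `"coexpression_model"`: `adjacency`, `tom`,
#'   `soft_power`, `type`.
#' @export
adjacency_tom <- function(expr, soft_power, type = c("signed", "unsigned")) {
  assert_matrix_like(expr)
  type <- match.arg(type)
  if (soft_power < 1) stop("`soft_power` must be >= 1")
  r <- stats::cor(t(expr))
  if (anyNA(r)) {
    bad <- which(is.na(r), arr.ind = TRUE)[1, ]
    stop(sprintf("correlation is NA for gene pair (%s, %s)",
                 rownames(r)[bad[1]], colnames(r)[bad[2]]))
  }
  a <- if (type == "unsigned") abs(r)^soft_power else ((1 + r) / 2)^soft_power
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- pmin(pmax((tom + t(tom)) / 2, 0), 1)
  dimnames(tom) <- dimnames(a) <- dimnames(r)
  structure(list(adjacency = a, tom = tom, soft_power = soft_power,
                 type = type), class = "coexpression_model")
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static cut at
#' `cut_height` (default 0.95: the cut sits just under the top of the tree,
#' separating major branches while leaving diffuse background genes in a
#' large unassigned pool); clusters smaller than `min_module_size` go to the unassigned
#' ("grey") pool; modules whose eigengenes correlate above
#' `1 - merge_height` are merged. Labels are `<prefix>1, <prefix>2, ...` in
#' decreasing module size; unassigned genes are labelled `"grey"`.
#'
#' @param model A `"coexpression_model"` from [adjacency_tom()].
#' @param expr The expression matrix the model was built from.
#' @param cut_height Static tree-cut height on 1 - TOM (default 0.95).
#' @param min_module_size Minimum genes per module (default 30).
#' @param merge_height Eigengene dissimilarity below which modules merge
#'   (default 0.25, i.e. merge when cor > 0.75).
#' @param label_prefix Module label prefix (default "M"; use "V"/"F" for
#'   organ-wise runs).
#' @return List of class `"module_set"`: `module_of_gene` (named character),
#'   `modules` (sizes), `eigengenes` (module x sample), `label_prefix`.
#' @export
detect_modules <- function(model, expr, cut_height = 0.95,
                           min_module_size = 30, merge_height = 0.25,
                           label_prefix = "M") {
  stopifnot(inherits(model, "coexpression_model"))
  assert_matrix_like(expr)
  d <- 1 - model$tom
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  assign <- ifelse(cl %in% keep, as.character(cl), "grey")
  names(assign) <- rownames(model$tom)
  if (all(assign == "grey")) {
    warning("all genes unassigned at these parameters")
    return(structure(list(module_of_gene = assign,
                          modules = integer(),
                          eigengenes = NULL,
                          label_prefix = label_prefix),
                     class = "module_set"))
  }
  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(assign), "grey")
    if (length(mods) < 2) break
    eg <- eigengene_matrix(expr, assign, mods)
    cc <- stats::cor(t(eg))
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - merge_height) break
    assign[assign == mods[mx[2]]] <- mods[mx[1]]
  }
  mods <- setdiff(unique(assign), "grey")
  ord <- mods[order(-vapply(mods, function(m) sum(assign == m), numeric(1)),
                    mods)]
  relabel <- stats::setNames(paste0(label_prefix, seq_along(ord)), ord)
  assign[assign != "grey"] <- relabel[assign[assign != "grey"]]
  eg <- eigengene_matrix(expr, assign, unname(relabel))
  structure(list(
    module_of_gene = assign,
    modules = vapply(unname(relabel), function(m) sum(assign == m), integer(1)),
    eigengenes = eg,
    label_prefix = label_prefix
  ), class = "module_set")
}

# First principal component of each module's standardized expression, sign
# oriented to correlate positively with the module mean profile.
eigengene_matrix <- function(expr, assign, mods) {
  eg <- t(vapply(mods, function(m) {
    x <- expr[names(assign)[assign == m], , drop = FALSE]
    xs <- t(scale(t(x)))
    xs[is.na(xs)] <- 0
    if (nrow(xs) == 1) return(as.numeric(xs))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    e
  }, numeric(ncol(expr))))
  rownames(eg) <- mods
  colnames(eg) <- colnames(expr)
  eg
}

#' Module eigengenes
#'
#' Per-module first principal component of the standardized member
#' expression across samples, sign-oriented to correlate positively with the
#' module mean profile. A single-gene module's eigengene is the standardized
#' gene itself.
#'
#' @param expr Expression matrix, genes x samples.
#' @param module_set A `"module_set"` from [detect_modules()].
#' @return Matrix, modules x samples.
#' @export
module_eigengenes <- function(expr, module_set) {
  stopifnot(inherits(module_set, "module_set"))
  if (!length(module_set$modules)) stop("empty module set")
  eigengene_matrix(expr, module_set$module_of_gene,
                   names(module_set$modules))
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each environmental
#' trait; p-values from the t distribution with n - 2 degrees of freedom.
#'
#' @param eigengenes Matrix, modules x samples.
#' @param trait_table data.frame with one row per sample (aligned to the
#'   eigengene columns) and numeric trait columns (e.g. CHILLING, LOD).
#' @return data.frame: `module`, `trait`, `r`, `p`.
#' @export
module_trait_correlation <- function(eigengenes, trait_table) {
  traits <- trait_table[, vapply(trait_table, is.numeric, logical(1)),
                        drop = FALSE]
  if (nrow(traits) != ncol(eigengenes)) {
    stop("trait rows must align with eigengene samples")
  }
  out <- expand.grid(module = rownames(eigengenes), trait = names(traits),
                     stringsAsFactors = FALSE)
  n <- ncol(eigengenes)
  res <- mapply(function(m, tr) {
    y <- traits[[tr]]
    if (stats::sd(y) == 0) stop(sprintf("trait '%s' is constant", tr))
    r <- stats::cor(eigengenes[m, ], y)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    p <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
    c(r = r, p = p)
  }, out$module, out$trait)
  out$r <- res["r", ]
  out$p <- res["p", ]
  out
}

#' Hypergeometric GO-term enrichment per module
#'
#' One-sided hypergeometric tail P(X >= k) for each annotation term
#' represented in a module, with BH adjustment across terms within the
#' module.
#'
#' @param module_genes Character vector of module gene ids.
#' @param annotation data.frame with columns `gene_id`, `term`.
#' @param background Character vector of background gene ids (superset of
#'   the module).
#' @return data.frame: `term`, `k_in_module`, `K_in_background`,
#'   `module_size`, `background_size`, `p_hypergeom`, `fdr`.
#' @export
hypergeom_enrichment <- function(module_genes, annotation, background) {
  module_genes <- unique(module_genes)
  background <- unique(background)
  if (!all(module_genes %in% background)) {
    stop("`background` must contain all module genes")
  }
  if (!length(module_genes)) {
    return(data.frame(term = character(), k_in_module = integer(),
                      K_in_background = integer(), module_size = integer(),
                      background_size = integer(), p_hypergeom = numeric(),
                      fdr = numeric()))
  }
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  dropped <- setdiff(unique(annotation$term), unique(ann$term))
  if (length(dropped)) {
    warning("term(s) absent from background skipped: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  n_bg <- length(background)
  n_mod <- length(module_genes)
  terms <- sort(unique(ann$term[ann$gene_id %in% module_genes]))
  if (!length(terms)) {
    return(data.frame(term = character(), k_in_module = integer(),
                      K_in_background = integer(), module_size = integer(),
                      background_size = integer(), p_hypergeom = numeric(),
                      fdr = numeric()))
  }
  rows <- lapply(terms, function(tm) {
    genes_tm <- unique(ann$gene_id[ann$term == tm])
    k <- length(intersect(genes_tm, module_genes))
    K <- length(genes_tm)
    p <- stats::phyper(k - 1, K, n_bg - K, n_mod, lower.tail = FALSE)
    data.frame(term = tm, k_in_module = k, K_in_background = K,
               module_size = n_mod, background_size = n_bg, p_hypergeom = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_hypergeom)
  out
}
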