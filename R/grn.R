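#' Partition genes into shared and organ-specific sets
#'
#' Presence in an organ means normalized expression at or above `min_expr`
#' in at least `min_samples` of that organ's samples. Genes present in both
#' organs are shared, genes present in exactly one are organ-specific, and
#' genes present in neither are dropped.
#'
#' @param expr_flower,expr_vegetative Normalized expression matrices, genes
#'   x samples; gene-id namespaces must overlap.
#' @param min_expr Presence threshold on the expression scale (default 1).
#' @param min_samples Minimum samples at or above the threshold (default 2).
#' @return List: `shared`, `flower_specific`, `vegetative_specific`
#'   (disjoint sorted character vectors).
#' @export
partition_genes <- function(expr_flower, expr_vegetative,
                            min_expr = 1, min_samples = 2) {
  assert_matrix_like(expr_flower)
  assert_matrix_like(expr_vegetative)
  common_space <- union(rownames(expr_flower), rownames(expr_vegetative))
  if (!length(intersect(rownames(expr_flower), rownames(expr_vegetative)))) {
    stop("gene-id namespaces of the two matrices do not overlap")
  }
  present <- function(m, g) {
    g %in% rownames(m) &&
      sum(m[g, ] >= min_expr) >= min_samples
  }
  in_f <- vapply(common_space, present, logical(1), m = expr_flower)
  in_v <- vapply(common_space, present, logical(1), m = expr_vegetative)
  list(
    shared = sort(common_space[in_f & in_v]),
    flower_specific = sort(common_space[in_f & !in_v]),
    vegetative_specific = sort(common_space[!in_f & in_v])
  )
}

#' GRN parameter set
#'
#' @param ntrees Trees per target-gene forest (default 500).
#' @param thresholds Named importance thresholds per network context
#'   (defaults: flower 0.30, vegetative 0.36, shared 0.27).
#' @param seed Integer seed for the tree ensembles.
#' @return List of class `"grn_params"`.
#' @export
grn_params <- function(ntrees = 500,
                       thresholds = c(flower = 0.30, vegetative = 0.36,
                                      shared = 0.27),
                       seed = 1L) {
  stopifnot(ntrees >= 1, all(thresholds > 0))
  structure(list(ntrees = ntrees, thresholds = thresholds, seed = seed),
            class = "grn_params")
}

#' Tree-ensemble regulator importances (GENIE3-style)
#'
#' For each target gene (every non-regulator gene), a Random-Forest
#' regression of its standardized expression profile on the regulator
#' profiles is fitted (`ntrees` trees, `floor(sqrt(#regulators))` candidate
#' features per split); the importance of a regulator is its share of the
#' total impurity (variance) reduction, normalized so each target's
#' importances sum to 1. Seeded and deterministic.
#'
#' @param expr Expression matrix, genes x samples (regulators included).
#' @param regulator_ids Regulator gene ids present in `expr` (>= 2).
#' @param params A [grn_params()].
#' @return Numeric matrix, regulators x targets, columns summing to 1.
#' @export
genie3_importances <- function(expr, regulator_ids, params = grn_params()) {
  assert_matrix_like(expr)
  stopifnot(inherits(params, "grn_params"))
  if (length(regulator_ids) < 2) stop("need >= 2 regulators")
  if (!all(regulator_ids %in% rownames(expr))) {
    stop("regulator(s) missing from the expression matrix: ",
         paste(setdiff(regulator_ids, rownames(expr)), collapse = ", "))
  }
  targets <- setdiff(rownames(expr), regulator_ids)
  reg_expr <- t(expr[regulator_ids, , drop = FALSE])
  colnames(reg_expr) <- regulator_ids
  mtry <- max(1L, floor(sqrt(length(regulator_ids))))
  w <- matrix(0, length(regulator_ids), length(targets),
              dimnames = list(regulator_ids, targets))
  for (ti in seq_along(targets)) {
    y <- as.numeric(scale(expr[targets[ti], ]))
    if (anyNA(y) || stats::sd(y) == 0) {
      y <- rep(0, ncol(expr))
    }
    dat <- data.frame(reg_expr, y = y, check.names = FALSE)
    rf <- ranger::ranger(
      dependent.variable.name = "y", data = dat,
      num.trees = params$ntrees, mtry = mtry,
      importance = "impurity", respect.unordered.factors = FALSE,
      num.threads = 1, seed = derive_seed(params$seed, ti))
    imp <- rf$variable.importance[regulator_ids]
    imp[is.na(imp) | imp < 0] <- 0
    s <- sum(imp)
    w[, ti] <- if (s > 0) imp / s else rep(1 / length(imp), length(imp))
  }
  w
}

#' Threshold an importance matrix into regulatory edges
#'
#' Retains regulator-target pairs whose importance strictly exceeds the
#' context threshold (flower 0.30, vegetative 0.36, shared 0.27 by default).
#'
#' @param weights Importance matrix, regulators x targets.
#' @param network_context One of the names of `params$thresholds`.
#' @param params A [grn_params()].
#' @return data.frame: `regulator`, `target`, `weight`, `network`.
#' @export
threshold_edges <- function(weights, network_context, params = grn_params()) {
  stopifnot(inherits(params, "grn_params"))
  if (!network_context %in% names(params$thresholds)) {
    stop("unknown network context: ", network_context)
  }
  tau <- params$thresholds[[network_context]]
  idx <- which(weights > tau, arr.ind = TRUE)
  out <- data.frame(
    regulator = rownames(weights)[idx[, 1]],
    target = colnames(weights)[idx[, 2]],
    weight = weights[idx],
    network = rep(network_context, nrow(idx))
  )
  out <- out[order(out$target, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Edge strength class from importance weight
#'
#' @param weight Positive importance weights.
#' @return Character vector: `"weak"` (< 0.3), `"moderate"` (0.3--0.5,
#'   boundaries inclusive), `"strong"` (> 0.5).
#' @export
classify_edge_strength <- function(weight) {
  stopifnot(all(weight > 0))
  ifelse(weight < 0.3, "weak", ifelse(weight <= 0.5, "moderate", "strong"))
}

#' Default BiFC interaction table
#'
#' Symmetric pairwise interaction outcomes among the DAM/SVP regulators from
#' in-planta fluorescence-complementation assays: positive SVP1-DAM3,
#' SVP1-DAM5, SVP1-DAM6 and DAM5-DAM6; negative DAM6-DAM3; everything else
#' untested. Fully overridable by supplying your own table.
#'
#' @return data.frame: `reg_a`, `reg_b`, `outcome`.
#' @export
default_bifc_table <- function() {
  data.frame(
    reg_a = c("SVP1", "SVP1", "SVP1", "DAM5", "DAM6"),
    reg_b = c("DAM3", "DAM5", "DAM6", "DAM6", "DAM3"),
    outcome = c("positive", "positive", "positive", "positive", "negative")
  )
}

bifc_lookup <- function(bifc, a, b) {
  hit <- (bifc$reg_a == a & bifc$reg_b == b) |
    (bifc$reg_a == b & bifc$reg_b == a)
  if (!any(hit)) "untested" else bifc$outcome[which(hit)[1]]
}

#' Annotate edges with dimer type and BiFC validation
#'
#' Within each network context and target, regulators retained after
#' thresholding are combined: every BiFC-positive pair among them becomes a
#' single heterodimer edge carrying both regulator ids (weight = mean of the
#' pair, `bifc_validated = TRUE`); regulators not consumed by a positive
#' pair stay as homodimer edges. BiFC-negative pairs are never merged.
#'
#' @param edges data.frame from [threshold_edges()].
#' @param bifc BiFC table (`reg_a`, `reg_b`, `outcome`); default
#'   [default_bifc_table()].
#' @return data.frame: `regulators` (single id or "A+B"), `target`,
#'   `weight`, `network`, `dimer`, `bifc_validated`, `strength`.
#' @export
annotate_dimers <- function(edges, bifc = default_bifc_table()) {
  if (!nrow(edges)) {
    return(data.frame(regulators = character(), target = character(),
                      weight = numeric(), network = character(),
                      dimer = character(), bifc_validated = logical(),
                      strength = character()))
  }
  key <- interaction(edges$network, edges$target, drop = TRUE)
  rows <- lapply(split(edges, key), function(e) {
    regs <- e$regulator
    wts <- stats::setNames(e$weight, regs)
    used <- character(0)
    out <- list()
    if (length(regs) >= 2) {
      prs <- utils::combn(sort(regs), 2, simplify = FALSE)
      for (pr in prs) {
        if (any(pr %in% used)) next
        if (bifc_lookup(bifc, pr[1], pr[2]) == "positive") {
          out[[length(out) + 1]] <- data.frame(
            regulators = paste(pr, collapse = "+"), target = e$target[1],
            weight = mean(wts[pr]), network = e$network[1],
            dimer = "heterodimer", bifc_validated = TRUE)
          used <- c(used, pr)
        }
      }
    }
    for (r in setdiff(regs, used)) {
      out[[length(out) + 1]] <- data.frame(
        regulators = r, target = e$target[1], weight = wts[[r]],
        network = e$network[1], dimer = "homodimer", bifc_validated = FALSE)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  out$strength <- classify_edge_strength(out$weight)
  out <- out[order(out$network, out$target, out$regulators), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter GRN edges by target GO annotation
#'
#' Computes hypergeometric enrichment of the network's target set against
#' the annotation background, retains terms with BH-adjusted p below
#' `alpha`, and keeps edges whose target carries at least one retained term.
#' With an empty annotation the edge list passes through with a warning.
#' The returned data.frame carries a logical `visual` column: the full edge
#' list is preserved, `visual = TRUE` marks the GO-filtered display set.
#'
#' @param edges Annotated edge data.frame (from [annotate_dimers()] or
#'   [threshold_edges()]).
#' @param annotation data.frame `gene_id`, `term`.
#' @param background Background gene ids (default: all annotated genes plus
#'   the edge targets).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return `edges` with an added `visual` column.
#' @export
go_filter_targets <- function(edges, annotation,
                              background = NULL, alpha = 0.05) {
  if (is.null(annotation) || !nrow(annotation)) {
    warning("empty annotation; GO filter is a pass-through")
    edges$visual <- TRUE
    return(edges)
  }
  if (is.null(background)) {
    background <- union(unique(annotation$gene_id), unique(edges$target))
  }
  edges$visual <- FALSE
  for (ctx in unique(edges$network)) {
    tg <- unique(edges$target[edges$network == ctx])
    enr <- hypergeom_enrichment(tg, annotation, background)
    kept_terms <- enr$term[enr$fdr < alpha]
    ok_genes <- unique(annotation$gene_id[annotation$term %in% kept_terms])
    edges$visual[edges$network == ctx & edges$target %in% ok_genes] <- TRUE
  }
  edges
}
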