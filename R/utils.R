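# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic entry points funnel through this so
# generators are pure functions of (arguments, seed).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Derive a stage sub-seed from a global pipeline seed
#'
#' Deterministic fan-out so each pipeline stage is independently
#' reproducible: `sub = (seed * 7919 + stage_index * 104729) mod (2^31 - 1)`.
#'
#' @param seed Global integer seed.
#' @param stage_index Integer index of the stage (>= 1).
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(stage_index) * 104729) %%
               2147483647)
}

# Shared argument checks -----------------------------------------------------

# Per-group row means that stay a genes x groups matrix even for one gene.
row_group_means <- function(m, groups, levels = unique(groups)) {
  out <- vapply(levels, function(g) {
    rowMeans(m[, groups == g, drop = FALSE])
  }, numeric(nrow(m)))
  if (!is.matrix(out)) {
    out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), levels))
  }
  out
}

assert_matrix_like <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("`%s` must be a matrix with gene rownames and sample colnames",
                 name))
  }
  if (anyDuplicated(rownames(x))) stop(sprintf("`%s` has duplicated gene ids", name))
  invisible(x)
}
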