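# Two planted blocks with high within- and zero between-correlation, plus
# optional independent background genes.
block_expr <- function(n_per = 50, n_noise = 0, n_samples = 30, seed = 44) {
  set.seed(seed)
  lat1 <- rnorm(n_samples)
  lat2 <- rnorm(n_samples)
  m <- rbind(
    t(sapply(seq_len(n_per), function(i) lat1 + rnorm(n_samples, sd = 0.2))),
    t(sapply(seq_len(n_per), function(i) lat2 + rnorm(n_samples, sd = 0.2))))
  if (n_noise > 0) {
    m <- rbind(m, matrix(rnorm(n_noise * n_samples), n_noise, n_samples))
  }
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      paste0("s", seq_len(n_samples)))
  m
}

test_that("TOM matches a brute-force evaluation of the formula", {
  x <- toy_expr()[1:4, ]
  model <- adjacency_tom(x, soft_power = 2, type = "unsigned")
  a <- abs(cor(t(x)))^2
  diag(a) <- 0
  n <- nrow(a)
  tom_brute <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { tom_brute[i, j] <- 1; next }
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    den <- min(sum(a[i, ]), sum(a[j, ])) + 1 - a[i, j]
    tom_brute[i, j] <- num / den
  }
  expect_equal(unname(model$tom), tom_brute, tolerance = 1e-12)
})

test_that("TOM invariants hold: symmetry, range, unit diagonal, extremes", {
  x <- block_expr(10, 5)
  model <- adjacency_tom(x, 6)
  expect_equal(model$tom, t(model$tom))
  expect_true(all(model$tom >= 0 & model$tom <= 1))
  expect_equal(unname(diag(model$tom)), rep(1, nrow(x)))
  # two perfectly correlated genes in isolation
  pair <- rbind(a = 1:10, b = (1:10) * 2 + 3)
  colnames(pair) <- paste0("s", 1:10)
  mp <- adjacency_tom(pair + 0, 6, type = "unsigned")
  expect_equal(unname(mp$adjacency[1, 2]), 1, tolerance = 1e-10)
  expect_equal(unname(mp$tom[1, 2]), 1, tolerance = 1e-10)
  expect_error(adjacency_tom(x, 0.5), ">= 1")
})

test_that("independent genes have near-zero TOM at large sample size", {
  set.seed(8)
  x <- matrix(rnorm(20 * 400), 20, 400,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:400)))
  model <- adjacency_tom(x, 6, type = "unsigned")
  off <- model$tom[upper.tri(model$tom)]
  expect_lt(max(off), 0.05)
})

test_that("soft power selection reports the scale-free fit and falls back", {
  x <- block_expr(40, 40, n_samples = 40)
  res <- suppressWarnings(
    soft_threshold_power(x, candidate_powers = 1:12, target_r2 = 0.5))
  expect_true(res$power >= 1)
  expect_true(all(c("power", "r_squared", "slope") %in% names(res$fit_table)))
  # white noise never reaches the target: fallback 6 with warning
  set.seed(2)
  wn <- matrix(rnorm(30 * 20), 30, 20,
               dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  expect_warning(res2 <- soft_threshold_power(wn, target_r2 = 0.999), "using 6")
  expect_equal(res2$power, 6)
  wn[1, ] <- 1
  expect_error(soft_threshold_power(wn), "constant genes")
})

test_that("two planted blocks are recovered as exactly two modules", {
  skip_if_not_installed("mclust")
  x <- block_expr(50, 0)
  model <- adjacency_tom(x, 6)
  ms <- detect_modules(model, x, min_module_size = 30)
  expect_equal(length(ms$modules), 2)
  truth <- rep(c("A", "B"), each = 50)
  expect_equal(mclust::adjustedRandIndex(truth, ms$module_of_gene), 1)
  # labels ordered by size, prefix honoured
  ms2 <- detect_modules(model, x, min_module_size = 30, label_prefix = "V")
  expect_setequal(names(ms2$modules), c("V1", "V2"))
})

test_that("identical planted blocks merge into one module", {
  set.seed(3)
  lat <- rnorm(30)
  x <- t(sapply(1:60, function(i) lat + rnorm(30, sd = 0.2)))
  dimnames(x) <- list(sprintf("g%02d", 1:60), paste0("s", 1:30))
  model <- adjacency_tom(x, 6)
  ms <- detect_modules(model, x, min_module_size = 10)
  expect_equal(length(ms$modules), 1)
})

test_that("oversized minimum module size leaves all genes unassigned", {
  x <- block_expr(20, 0)
  model <- adjacency_tom(x, 6)
  expect_warning(ms <- detect_modules(model, x, min_module_size = 1000),
                 "unassigned")
  expect_true(all(ms$module_of_gene == "grey"))
})

test_that("eigengenes summarize modules with the documented orientation", {
  set.seed(21)
  lat <- rnorm(20)
  x <- t(sapply(1:10, function(i) 5 + 2 * lat + rnorm(20, sd = 0.05)))
  dimnames(x) <- list(paste0("g", 1:10), paste0("s", 1:20))
  model <- adjacency_tom(x, 6)
  ms <- detect_modules(model, x, min_module_size = 5)
  eg <- module_eigengenes(x, ms)
  # eigengene tracks the standardized common profile
  expect_gt(cor(eg[1, ], lat), 0.99)
  # orientation: positively correlated with module mean expression
  std <- t(scale(t(x)))
  expect_gt(cor(eg[1, ], colMeans(std)), 0)
  # negating all members flips the eigengene
  xneg <- -x
  msneg <- detect_modules(adjacency_tom(xneg, 6), xneg, min_module_size = 5)
  expect_gt(cor(module_eigengenes(xneg, msneg)[1, ], -lat), 0.99)
})

test_that("module-trait correlation matches cor.test and a permutation check", {
  set.seed(10)
  eg <- rbind(M1 = rnorm(20))
  colnames(eg) <- paste0("s", 1:20)
  tr <- data.frame(CHILLING = eg[1, ] * 2 + rnorm(20, sd = 0.5),
                   LOD = rnorm(20))
  mt <- module_trait_correlation(eg, tr)
  ct <- cor.test(eg[1, ], tr$CHILLING)
  expect_equal(mt$r[mt$trait == "CHILLING"], unname(ct$estimate),
               tolerance = 1e-10)
  expect_equal(mt$p[mt$trait == "CHILLING"], ct$p.value, tolerance = 1e-10)
  # permutation p within Monte-Carlo error for the null trait
  obs <- abs(mt$r[mt$trait == "LOD"])
  perm <- replicate(1000, abs(cor(eg[1, ], sample(tr$LOD))))
  p_perm <- mean(perm >= obs)
  expect_lt(abs(p_perm - mt$p[mt$trait == "LOD"]), 0.08)
  expect_error(module_trait_correlation(eg, data.frame(CHILLING = rep(1, 20))),
               "constant")
})

test_that("exact trait tracking gives |r| = 1 and orthogonal traits r = 0", {
  eg <- rbind(M1 = seq(-1, 1, length.out = 12))
  colnames(eg) <- paste0("s", 1:12)
  tr <- data.frame(CHILLING = eg[1, ],
                   ORTHO = rep(c(-1, 1), 6) - mean(rep(c(-1, 1), 6)))
  tr$ORTHO <- tr$ORTHO - sum(tr$ORTHO * eg[1, ]) / sum(eg[1, ]^2) * eg[1, ]
  mt <- module_trait_correlation(eg, tr)
  expect_equal(mt$r[mt$trait == "CHILLING"], 1, tolerance = 1e-10)
  expect_equal(mt$r[mt$trait == "ORTHO"], 0, tolerance = 1e-10)
})

test_that("hypergeometric enrichment equals exact combinatorial arithmetic", {
  bg <- paste0("g", 1:100)
  ann <- data.frame(gene_id = paste0("g", 1:5), term = "GO:0001")
  res <- hypergeom_enrichment(paste0("g", 1:5), ann, bg)
  expect_equal(res$p_hypergeom, 1 / choose(100, 5))
  # module = all annotated genes of a term covering the whole background
  ann2 <- data.frame(gene_id = bg, term = "GO:0002")
  res2 <- hypergeom_enrichment(bg, ann2, bg)
  expect_equal(res2$p_hypergeom, 1)
  expect_equal(nrow(hypergeom_enrichment(character(), ann, bg)), 0)
  expect_error(hypergeom_enrichment("zz", ann, bg), "background")
})
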