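test_that("TMM factors are unit for identical or depth-scaled libraries", {
  m <- matrix(c(100, 200, 300, 50), 4, 2,
              dimnames = list(paste0("g", 1:4), c("a", "b")))
  m[, 2] <- m[, 1]
  expect_equal(unname(tmm_factors(m)), c(1, 1))
  m2 <- m
  m2[, 2] <- 2 * m[, 1]  # pure depth difference
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM matches the brute-force trimmed-mean oracle", {
  toy <- matrix(c(100, 200, 300, 400,
                  100, 200, 300, 4000), 4, 2,
                dimnames = list(paste0("g", 1:4), c("a", "b")))
  expect_equal(unname(tmm_factors(toy)), unname(tmm_oracle(toy)),
               tolerance = 1e-10)
  set.seed(31)
  big <- matrix(rnbinom(200 * 5, mu = exp(runif(200, 3, 7)), size = 5),
                200, 5, dimnames = list(paste0("g", 1:200), paste0("s", 1:5)))
  big <- big + 1L  # avoid zeros so the oracle and implementation see all genes
  expect_equal(unname(tmm_factors(big)), unname(tmm_oracle(big)),
               tolerance = 1e-10)
  expect_equal(exp(mean(log(tmm_factors(big)))), 1, tolerance = 1e-12)
})

test_that("TMM agrees with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  cts <- matrix(rnbinom(1000 * 6, mu = rep(exp(runif(1000, 3, 8)), 6), size = 10),
                1000, 6, dimnames = list(paste0("g", 1:1000), paste0("s", 1:6)))
  cts[1:40, 6] <- cts[1:40, 6] * 8L
  ed <- edgeR::calcNormFactors(edgeR::DGEList(cts), method = "TMM",
                               doWeighting = FALSE)$samples$norm.factors
  expect_equal(unname(tmm_factors(cts)), ed, tolerance = 1e-8)
})

test_that("TMM rejects degenerate input", {
  m <- matrix(c(1, 2, 0, 0), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_error(tmm_factors(m), "all-zero")
  expect_error(tmm_factors(m[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("log-CPM transform matches hand arithmetic and is depth-invariant", {
  m <- matrix(c(0, 100, 50, 150), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  f <- c(a = 1, b = 1)
  lc <- normalize_log_cpm(m, f)
  expect_equal(lc["g1", "a"], log2(0 + 1))
  expect_equal(lc["g2", "b"], log2(150 / 200 * 1e6 + 1))
  # doubling counts (and hence library sizes) leaves values unchanged
  expect_equal(normalize_log_cpm(2L * m, f), lc, tolerance = 1e-12)
  expect_error(normalize_log_cpm(m, c(x = 1, y = 1)), "do not match")
})

test_that("batch correction removes planted batch variance, keeps group means", {
  sim <- simulate_expression(simulation_config(
    n_genes = 150, bias_fraction = 0, batch_effect_sd = 1,
    noise_dispersion = 0.05, seed = 17))
  f <- tmm_factors(sim$counts)
  lg <- normalize_log_cpm(sim$counts, f)
  grp <- paste(sim$metadata$organ, sim$metadata$timepoint, sep = ".")
  batch_var <- function(m) {
    mean(vapply(seq_len(nrow(m)), function(i) {
      resid <- m[i, ] - ave(m[i, ], grp)
      summary(lm(resid ~ sim$metadata$batch))$r.squared
    }, numeric(1)))
  }
  before <- batch_var(lg)
  corrected <- correct_batch(lg, sim$metadata$batch, grp)
  after <- batch_var(corrected)
  expect_gt(before, 0.5)
  expect_lt(after, 0.05)
  # group means preserved
  gm <- function(m) vapply(unique(grp), function(g) {
    rowMeans(m[, grp == g, drop = FALSE])
  }, numeric(nrow(m)))
  expect_equal(gm(corrected), gm(lg), tolerance = 1e-8)
})

test_that("batch correction no-ops on single or confounded batches", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  grp <- rep(c("x", "y"), each = 5)
  expect_identical(correct_batch(m, rep("A", 10), grp), m)
  expect_warning(out <- correct_batch(m, grp, grp), "confounded")
  expect_identical(out, m)
  # zero-variance gene passes through without numerical failure
  m2 <- m
  m2[1, ] <- 3
  batch <- rep(c("A", "B"), 5)
  expect_silent(correct_batch(m2, batch, grp))
})

test_that("per-gene F-test matches the hand ANOVA oracle", {
  y <- c(4.1, 4.4, 3.9, 6.2, 6.0, 6.5)
  tp <- rep(c("t1", "t2"), each = 3)
  m <- rbind(gene = y)
  colnames(m) <- paste0("s", 1:6)
  rec <- test_de(m, tp)
  oracle <- anova(lm(y ~ factor(tp)))
  expect_equal(rec$p_value[1], oracle$`Pr(>F)`[1], tolerance = 1e-12)
  expect_equal(rec$log2fc[1], mean(y[4:6]) - mean(y[1:3]), tolerance = 1e-12)
})

test_that("flat genes get p = 1 and planted steps recover their fold change", {
  m <- rbind(flat = rep(5, 9),
             step = rep(c(1, 1, 2), each = 3))
  colnames(m) <- paste0("s", 1:9)
  tp <- rep(c("t1", "t2", "t3"), each = 3)
  rec <- test_de(m, tp)
  expect_equal(unique(rec$p_value[rec$gene_id == "flat"]), 1)
  expect_equal(rec$log2fc[rec$gene_id == "step" &
                            rec$contrast == "t3_vs_t1"], 1)
  # single-replicate timepoints are dropped with a warning
  m1 <- m[, 1:7]
  tp1 <- tp[1:7]
  expect_warning(test_de(m1, tp1), "single replicate")
})

test_that("BH adjustment wraps the step-up procedure and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, NA)), "NA")
  expect_error(bh_adjust(1.2), "0, 1")
})

test_that("DEG filtering applies inclusive FC and FDR gates", {
  rec <- data.frame(
    gene_id = rep(c("a", "b", "c", "d", "e"), each = 1),
    contrast = "t2_vs_t1",
    log2fc = c(log2(1.4), 2, 0.1, -1, 0.6),
    p_value = c(0.001, 0.2, 0.001, 0.001, 0.001),
    fdr = c(0.01, 0.2, 0.01, 0.01, 0.01))
  got <- filter_deg(rec, fc_min = 1.4, fdr_max = 0.05)
  expect_setequal(got, c("a", "d", "e"))  # boundary FC retained; b fails FDR
  expect_error(filter_deg(rec, fc_min = 0.9), ">= 1")
  # brute-force check on the same records
  brute <- sapply(split(rec, rec$gene_id), function(df) {
    max(abs(df$log2fc)) >= log2(1.4) && min(df$fdr) <= 0.05
  })
  expect_setequal(got, names(brute)[brute])
})

test_that("DEG filtering is monotone in both thresholds", {
  set.seed(5)
  rec <- data.frame(
    gene_id = rep(sprintf("g%02d", 1:40), each = 2),
    contrast = rep(c("t2_vs_t1", "t3_vs_t1"), 40),
    log2fc = rnorm(80),
    p_value = runif(80))
  rec$fdr <- bh_adjust(rec$p_value)
  base <- filter_deg(rec, 1.3, 0.2)
  for (fc in c(1.5, 2)) {
    expect_true(all(filter_deg(rec, fc, 0.2) %in% base))
  }
  for (q in c(0.1, 0.01)) {
    expect_true(all(filter_deg(rec, 1.3, q) %in% base))
  }
})

test_that("planted DE genes are recovered with controlled error", {
  res <- vapply(1:5, function(s) {
    sim <- simulate_expression(simulation_config(
      n_genes = 300, module_sizes = 60, trait_profiles = "chilling_up",
      module_loading = 1.5 * log(2) / 2, noise_dispersion = 0.05,
      bias_fraction = 0, seed = s))
    f <- tmm_factors(sim$counts)
    lg <- normalize_log_cpm(sim$counts, f)
    grp <- paste(sim$metadata$organ, sim$metadata$timepoint, sep = ".")
    lg <- correct_batch(lg, sim$metadata$batch, grp)
    sel <- sim$metadata$organ == "vegetative"
    rec <- test_de(lg[, sel], sim$metadata$timepoint[sel])
    hits <- filter_deg(rec, 1.4, 0.05)
    planted <- names(sim$truth$module_of_gene)[
      sim$truth$module_of_gene == "M1"]
    c(sens = mean(planted %in% hits), fdr = mean(!(hits %in% planted)))
  }, numeric(2))
  expect_gte(mean(res["sens", ]), 0.9)
  expect_lte(mean(res["fdr", ]), 0.1)
})

test_that("Venn partition satisfies its counting invariants", {
  a <- paste0("g", 1:10)
  b <- paste0("g", 6:12)
  vp <- venn_partition(a, b)
  expect_equal(vp$shared + vp$unique_a, length(unique(a)))
  expect_equal(vp$shared + vp$unique_b, length(unique(b)))
  expect_equal(venn_partition(a, a)[1:3], list(shared = 10, unique_a = 0,
                                               unique_b = 0))
  expect_equal(venn_partition(a, paste0("x", 1:3))[1:3],
               list(shared = 0, unique_a = 10, unique_b = 3))
  # sets sized like the two bud transcriptomes: totals follow by invariant
  vp2 <- list(shared = 5913, unique_a = 2969, unique_b = 2726)
  expect_equal(vp2$shared + vp2$unique_a, 8882)
  expect_equal(vp2$shared + vp2$unique_b, 8639)
})
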