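#' Simulation configuration for synthetic bud transcriptome data
#'
#' Collects the knobs of the synthetic-data generator. Defaults emulate the
#' study design the package targets: two bud organs sampled at six chilling
#' timepoints over two seasons (batches), three biological replicates,
#' negative-binomial counts, co-expression modules driven by the two
#' anti-correlated environmental covariates (CHILLING up, day length down),
#' a fraction of organ-biased genes, and a planted DAM/SVP regulator-target
#' network.
#'
#' @param n_genes Total number of genes (including regulators).
#' @param n_timepoints Number of chilling timepoints (default 6).
#' @param n_replicates Biological replicates per organ x timepoint (3--4).
#' @param organs Organ labels; first level is the reference for contrasts.
#' @param module_sizes Integer vector of planted module sizes.
#' @param trait_profiles Character vector, one per module, each in
#'   `c("chilling_up", "chilling_down", "lod_up", "lod_down", "none")`.
#' @param module_loading Log-scale loading of the module driver.
#' @param bias_fraction Fraction of genes with planted organ bias.
#' @param bias_effect Log2-scale organ offset of biased genes.
#' @param regulators Regulator gene labels (default DAM1--6, SVP1, SVP2).
#' @param n_targets_per_regulator Planted targets per regulator (0 disables
#'   the regulatory layer).
#' @param regulator_effect Log-scale effect of a regulator on its targets.
#' @param noise_dispersion Negative-binomial dispersion (1/size).
#' @param batch_effect_sd Gene-wise log-scale SD of per-batch offsets.
#' @param library_size_range Length-2 numeric, range of library-size factors.
#' @param batch_design `"by_replicate"` (default): replicates are split
#'   across the two seasons so batch is crossed with organ x timepoint, as
#'   when a timepoint is sampled in both years; `"by_timepoint"`: each
#'   timepoint belongs to one season (batch confounded with time).
#' @param cu_max,lod_start,lod_end Endpoints of the planted trait curves.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 500,
                              n_timepoints = 6,
                              n_replicates = 3,
                              organs = c("vegetative", "flower"),
                              module_sizes = integer(),
                              trait_profiles = character(),
                              module_loading = 1,
                              bias_fraction = 0,
                              bias_effect = 1.5,
                              regulators = c(paste0("DAM", 1:6), "SVP1", "SVP2"),
                              n_targets_per_regulator = 0,
                              regulator_effect = 1,
                              noise_dispersion = 0.05,
                              batch_effect_sd = 0.3,
                              library_size_range = c(0.7, 1.3),
                              batch_design = c("by_replicate", "by_timepoint"),
                              cu_max = 930,
                              lod_start = 12.85,
                              lod_end = 8.72,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_timepoints >= 2,
            n_replicates >= 1, length(organs) >= 1)
  if (length(module_sizes) != length(trait_profiles)) {
    stop("`module_sizes` and `trait_profiles` must have equal length")
  }
  if (sum(module_sizes) > n_genes) {
    stop("`module_sizes` sum exceeds `n_genes`")
  }
  if (bias_fraction < 0 || bias_fraction > 1) {
    stop("`bias_fraction` must be in [0, 1]")
  }
  if (noise_dispersion <= 0) stop("`noise_dispersion` must be > 0")
  batch_design <- match.arg(batch_design)
  ok <- c("chilling_up", "chilling_down", "lod_up", "lod_down", "none")
  if (!all(trait_profiles %in% ok)) {
    stop("unknown trait profile; use one of: ", paste(ok, collapse = ", "))
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate environmental trait curves over a chilling time course
#'
#' Linear trait curves for a winter sampling window: cumulative chilling
#' (CHILLING) rises from 0 to `cu_max`, day length (LOD) falls from
#' `lod_start` to `lod_end`. The two covariates are anti-correlated by
#' construction, as they are over a real autumn-winter window.
#'
#' @param n_timepoints Number of timepoints (>= 2).
#' @param cu_max Final cumulative chilling units (> 0).
#' @param lod_start,lod_end Day length in hours at the first and last
#'   timepoint; `lod_start` must exceed `lod_end`.
#' @return data.frame with columns `timepoint`, `CHILLING`, `LOD`.
#' @examples
#' simulate_traits(6, 930, 12.85, 8.72)
#' @export
simulate_traits <- function(n_timepoints, cu_max, lod_start, lod_end) {
  if (length(n_timepoints) != 1 || n_timepoints < 2) {
    stop("`n_timepoints` must be a single value >= 2")
  }
  if (cu_max <= 0) stop("`cu_max` must be > 0")
  if (lod_start <= lod_end) stop("`lod_start` must exceed `lod_end`")
  data.frame(
    timepoint = seq_len(n_timepoints),
    CHILLING = seq(0, cu_max, length.out = n_timepoints),
    LOD = seq(lod_start, lod_end, length.out = n_timepoints)
  )
}

#' Simulate an hourly temperature series
#'
#' Deterministic seasonal trend (cooling through the window) plus a diurnal
#' sinusoid and seeded Gaussian noise; a stand-in for station records.
#'
#' @param start_date First day of the series.
#' @param n_days Number of days (>= 1).
#' @param seed Integer seed.
#' @param mean_start,mean_end Daily mean temperature at the window ends (C).
#' @param diurnal_amplitude Half-range of the daily cycle (C).
#' @param noise_sd SD of the hourly Gaussian noise (C); 0 gives the pure
#'   deterministic series.
#' @return data.frame with columns `timestamp`, `temp_c` (24 rows per day).
#' @export
simulate_temperatures <- function(start_date, n_days, seed = 1L,
                                  mean_start = 12, mean_end = 2,
                                  diurnal_amplitude = 4, noise_sd = 1) {
  if (n_days < 1) stop("`n_days` must be >= 1")
  start_date <- as.Date(start_date)
  n <- 24L * as.integer(n_days)
  hour_of_day <- rep(0:23, n_days)
  day_idx <- rep(seq_len(n_days) - 1L, each = 24L)
  seasonal <- mean_start + (mean_end - mean_start) * day_idx / max(1, n_days - 1)
  diurnal <- diurnal_amplitude * sin(2 * pi * (hour_of_day - 9) / 24)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n, sd = noise_sd))
  } else {
    numeric(n)
  }
  data.frame(
    timestamp = as.POSIXct(paste(start_date + day_idx,
                                 sprintf("%02d:00:00", hour_of_day)), tz = "UTC"),
    temp_c = seasonal + diurnal + noise
  )
}

#' Simulate a bud expression count matrix with planted ground truth
#'
#' Generates a genes x samples negative-binomial count matrix over a
#' two-organ chilling time course with known structure: co-expression modules
#' tied to the CHILLING/LOD trait curves, organ-biased genes, gene-wise batch
#' offsets shared across organs, and a regulator-to-target layer in which
#' each target's log-mean receives an additive contribution from its
#' regulator's noise-free latent profile.
#'
#' Counts follow NB(mu, size = 1/dispersion) with
#' mu = library_factor * exp(baseline + module_loading * driver +
#' organ_bias + batch_offset + regulator_effect).
#'
#' @param config A [simulation_config()].
#' @return A list with elements `counts` (integer matrix, genes x samples),
#'   `metadata` (data.frame: sample_id, organ, timepoint, timepoint_cu,
#'   batch, replicate), `traits` (the trait curve table) and `truth` (list:
#'   `module_of_gene`, `bias_of_gene`, `grn_edges`, `trait_curves`,
#'   `regulator_latent`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_expression_impl(config))
}

simulate_expression_impl <- function(cfg) {
  n_reg <- if (cfg$n_targets_per_regulator > 0) length(cfg$regulators) else 0L
  n_other <- cfg$n_genes - n_reg
  if (n_other < sum(cfg$module_sizes)) {
    stop("`n_genes` too small for the requested modules and regulators")
  }
  gene_ids <- c(if (n_reg) cfg$regulators,
                sprintf("PRUPE_G%04d", seq_len(n_other)))

  traits <- simulate_traits(cfg$n_timepoints, cfg$cu_max,
                            cfg$lod_start, cfg$lod_end)
  chill_z <- as.numeric(scale(traits$CHILLING))
  lod_z <- as.numeric(scale(traits$LOD))

  organs <- cfg$organs
  meta <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      timepoint = seq_len(cfg$n_timepoints),
                      organ = organs, stringsAsFactors = FALSE)
  # two-season sampling design: batch crossed with timepoint (default) or
  # each timepoint collected in a single season
  if (cfg$batch_design == "by_replicate") {
    meta$batch <- ifelse(meta$replicate <= ceiling(cfg$n_replicates / 2),
                         "A", "B")
  } else {
    batch_of_tp <- rep(c("A", "B"), length.out = cfg$n_timepoints)
    meta$batch <- batch_of_tp[meta$timepoint]
  }
  meta$timepoint_cu <- traits$CHILLING[meta$timepoint]
  meta$sample_id <- sprintf("%s_T%d_R%d", substr(meta$organ, 1, 1),
                            meta$timepoint, meta$replicate)
  n_samples <- nrow(meta)

  # module membership: planted modules occupy the first non-regulator genes
  module_of_gene <- rep("none", cfg$n_genes)
  names(module_of_gene) <- gene_ids
  offset <- n_reg
  for (m in seq_along(cfg$module_sizes)) {
    idx <- offset + seq_len(cfg$module_sizes[m])
    module_of_gene[idx] <- paste0("M", m)
    offset <- offset + cfg$module_sizes[m]
  }

  driver_of_module <- function(profile) {
    switch(profile,
           chilling_up = chill_z, chilling_down = -chill_z,
           lod_up = lod_z, lod_down = -lod_z,
           none = rep(0, cfg$n_timepoints))
  }

  # organ bias: half of the biased genes flower-biased, half vegetative
  bias_of_gene <- rep("balanced", cfg$n_genes)
  names(bias_of_gene) <- gene_ids
  free <- which(module_of_gene == "none" & !(gene_ids %in% cfg$regulators))
  pool <- c(free, which(module_of_gene != "none"))
  n_bias <- round(cfg$bias_fraction * cfg$n_genes)
  if (n_bias > 0) {
    picked <- sample(pool, min(n_bias, length(pool)))
    half <- sample(picked, floor(length(picked) / 2))
    bias_of_gene[half] <- "flower"
    bias_of_gene[setdiff(picked, half)] <- "vegetative"
  }

  # regulator latent profiles: smooth temporal base + per-sample jitter,
  # noise-free (counts add NB noise on top)
  reg_latent <- NULL
  grn_edges <- data.frame(regulator = character(), target = character())
  if (n_reg) {
    reg_latent <- matrix(0, n_reg, n_samples,
                         dimnames = list(cfg$regulators, meta$sample_id))
    for (r in seq_len(n_reg)) {
      w <- stats::rnorm(2)
      base <- w[1] * chill_z + w[2] * lod_z
      reg_latent[r, ] <- base[meta$timepoint] + stats::rnorm(n_samples, sd = 0.5)
    }
    targets <- sprintf("PRUPE_G%04d", seq_len(min(
      n_other, n_reg * cfg$n_targets_per_regulator)))
    grn_edges <- data.frame(
      regulator = rep(cfg$regulators, each = cfg$n_targets_per_regulator)[
        seq_along(targets)],
      target = targets
    )
  }

  baseline <- stats::runif(cfg$n_genes, log(50), log(500))
  batch_levels <- unique(meta$batch)
  batch_off <- matrix(stats::rnorm(cfg$n_genes * length(batch_levels),
                                   sd = cfg$batch_effect_sd),
                      cfg$n_genes, length(batch_levels),
                      dimnames = list(gene_ids, batch_levels))
  lib_factor <- stats::runif(n_samples, cfg$library_size_range[1],
                             cfg$library_size_range[2])

  log2e <- log(2)
  log_mu <- matrix(baseline, cfg$n_genes, n_samples,
                   dimnames = list(gene_ids, meta$sample_id))
  for (m in seq_along(cfg$module_sizes)) {
    drv <- driver_of_module(cfg$trait_profiles[m])
    idx <- which(module_of_gene == paste0("M", m))
    log_mu[idx, ] <- log_mu[idx, ] +
      cfg$module_loading * rep(drv[meta$timepoint], each = length(idx))
  }
  is_flower <- meta$organ == "flower"
  bias_sign <- ifelse(bias_of_gene == "flower", 1,
                      ifelse(bias_of_gene == "vegetative", -1, 0))
  log_mu <- log_mu + (cfg$bias_effect * log2e / 2) *
    outer(bias_sign, ifelse(is_flower, 1, -1))
  log_mu <- log_mu + batch_off[, match(meta$batch, batch_levels)]
  if (nrow(grn_edges)) {
    for (i in seq_len(nrow(grn_edges))) {
      log_mu[grn_edges$target[i], ] <- log_mu[grn_edges$target[i], ] +
        cfg$regulator_effect * reg_latent[grn_edges$regulator[i], ]
    }
    # regulator counts track their own latent profile
    log_mu[cfg$regulators, ] <- log_mu[cfg$regulators, ] + reg_latent
  }

  mu <- sweep(exp(log_mu), 2, lib_factor, `*`)
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$noise_dispersion),
    nrow(mu), ncol(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"

  list(
    counts = counts,
    metadata = meta[, c("sample_id", "organ", "timepoint", "timepoint_cu",
                        "batch", "replicate")],
    traits = traits,
    truth = list(
      module_of_gene = module_of_gene,
      bias_of_gene = bias_of_gene,
      grn_edges = grn_edges,
      trait_curves = traits,
      regulator_latent = reg_latent
    )
  )
}
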