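#' Pipeline configuration
#'
#' Materializes all stage defaults into one validated list; unknown keys are
#' rejected. A resolved copy is written next to the outputs by
#' [run_pipeline()].
#'
#' @param outdir Output directory.
#' @param seed Global integer seed, fanned out to per-stage sub-seeds via
#'   [derive_seed()].
#' @param simulation A [simulation_config()] describing the synthetic inputs
#'   (the bundled demo mode); or NULL with `counts`/`metadata` supplied.
#' @param counts,metadata Optional paths to a counts TSV and metadata TSV
#'   (used when `simulation` is NULL).
#' @param stages Character vector of stages to run, a subset of
#'   `c("deg", "bias", "modules", "graph", "grn")` (environment traits are
#'   always computed).
#' @param fc_min,fdr_max Global DEG filter (defaults 1.4 / 0.05).
#' @param network_fc_min,network_fdr_max Stringent filter feeding the module
#'   and network stages (defaults 1.5 / 0.01).
#' @param soft_power Soft-threshold power; NULL selects it by the
#'   scale-free criterion.
#' @param adjacency_type `"signed"` (default) or `"unsigned"`.
#' @param min_module_size Minimum module size (default 30).
#' @param graph_k,graph_r_min Top-k graph parameters (defaults 5 / 0.75).
#' @param grn A [grn_params()].
#' @param regulators Regulator ids for the GRN stage.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir,
                            seed = 1L,
                            simulation = NULL,
                            counts = NULL,
                            metadata = NULL,
                            stages = c("deg", "bias", "modules", "graph", "grn"),
                            fc_min = 1.4, fdr_max = 0.05,
                            network_fc_min = 1.5, network_fdr_max = 0.01,
                            soft_power = 6,
                            adjacency_type = "signed",
                            min_module_size = 30,
                            graph_k = 5, graph_r_min = 0.75,
                            grn = grn_params(),
                            regulators = c(paste0("DAM", 1:6), "SVP1", "SVP2")) {
  known <- c("deg", "bias", "modules", "graph", "grn")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if (is.null(simulation) && (is.null(counts) || is.null(metadata))) {
    stop("either `simulation` or both `counts` and `metadata` are required")
  }
  structure(as.list(environment())[names(formals())],
            class = "pipeline_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes trait construction, normalization + DEG filtering, organ-bias
#' classification, module detection + module-trait correlation, the reduced
#' top-k graph, and GRN inference in order, honoring the configured stage
#' toggles. Every output is a TSV/JSON file; a manifest JSON listing each
#' file with its MD5 hash is written last, so identical config + seed give
#' identical manifests.
#'
#' @param config A [pipeline_config()].
#' @return The manifest as a named list (file -> md5), invisibly; files are
#'   written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  files <- character(0)
  stage <- ""
  tryCatch({
    # resolved config copy
    stage <- "config"
    cfg_json <- out("config_resolved.json")
    jsonlite::write_json(serialize_config(config), cfg_json,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, cfg_json)

    # inputs
    stage <- "inputs"
    if (!is.null(config$simulation)) {
      sim <- simulate_expression(config$simulation)
      counts <- sim$counts
      meta <- sim$metadata
      traits <- sim$traits
    } else {
      counts <- read_matrix_tsv(config$counts)
      meta <- read_table_tsv(config$metadata)
      traits <- data.frame(timepoint = sort(unique(meta$timepoint)),
                           CHILLING = sort(unique(meta$timepoint_cu)))
      traits$LOD <- seq(12.85, 8.72, length.out = nrow(traits))
    }
    rep <- validate_inputs(counts, meta)
    if (length(rep$failures)) {
      stop("input validation failed: ", paste(rep$failures, collapse = "; "))
    }
    files <- c(files, write_matrix_tsv(counts, out("counts.tsv")),
               write_table_tsv(meta, out("metadata.tsv")))

    # traits per sample
    stage <- "env"
    trait_by_sample <- data.frame(
      sample_id = meta$sample_id,
      CHILLING = traits$CHILLING[meta$timepoint],
      LOD = traits$LOD[meta$timepoint])
    files <- c(files, write_table_tsv(trait_by_sample, out("traits.tsv")))

    # normalization (always needed downstream)
    stage <- "normalize"
    f <- tmm_factors(counts)
    logcpm <- normalize_log_cpm(counts, f)
    grp <- paste(meta$organ, meta$timepoint, sep = ".")
    logcpm <- correct_batch(logcpm, meta$batch, grp)
    files <- c(files, write_matrix_tsv(round(logcpm, 6), out("log_cpm.tsv")))

    deg_sets <- list()
    for (org in unique(meta$organ)) {
      sel <- meta$organ == org
      rec <- test_de(logcpm[, sel, drop = FALSE], meta$timepoint[sel])
      deg_sets[[org]] <- list(
        records = rec,
        global = filter_deg(rec, config$fc_min, config$fdr_max),
        network = filter_deg(rec, config$network_fc_min, config$network_fdr_max))
    }

    if ("deg" %in% config$stages) {
      stage <- "deg"
      all_rec <- do.call(rbind, lapply(names(deg_sets), function(o) {
        cbind(organ = o, deg_sets[[o]]$records)
      }))
      files <- c(files, write_table_tsv(all_rec, out("deg_records.tsv")))
      orgs <- names(deg_sets)
      if (length(orgs) == 2) {
        vp <- venn_partition(deg_sets[[orgs[1]]]$global,
                             deg_sets[[orgs[2]]]$global)
        venn_json <- out("deg_venn.json")
        jsonlite::write_json(vp[c("shared", "unique_a", "unique_b")],
                             venn_json, auto_unbox = TRUE)
        files <- c(files, venn_json)
      }
    }

    if ("bias" %in% config$stages) {
      stage <- "bias"
      fitb <- fit_condition_model(logcpm, meta$organ, meta$timepoint)
      fitb$category <- classify_bias(fitb$coef_condition, fitb$p_condition)
      fitb$specificity <- call_specificity(logcpm, meta$organ)
      shared_idx <- fitb$specificity == "shared"
      feats <- group_mean_features(logcpm, meta$organ, meta$timepoint)
      pca <- pca_shared(feats[shared_idx, , drop = FALSE])
      r_pc1 <- pc_bias_correlation(pca$scores[, 1],
                                   fitb$coef_condition[shared_idx])
      files <- c(files, write_table_tsv(fitb, out("bias_table.tsv")))
      scores <- data.frame(gene_id = rownames(pca$scores),
                           round(pca$scores[, 1:3, drop = FALSE], 6))
      files <- c(files, write_table_tsv(scores, out("pca_scores.tsv")))
      bias_json <- out("bias_summary.json")
      jsonlite::write_json(
        list(pc1_coef_correlation = r_pc1,
             pc1_variance_explained = pca$variance_explained[1]),
        bias_json, auto_unbox = TRUE, digits = NA)
      files <- c(files, bias_json)
    }

    module_sets <- list()
    if (any(c("modules", "graph") %in% config$stages)) {
      stage <- "modules"
      for (org in names(deg_sets)) {
        genes <- deg_sets[[org]]$network
        if (length(genes) < config$min_module_size) next
        sel <- meta$organ == org
        ex <- logcpm[genes, sel, drop = FALSE]
        ex <- ex[apply(ex, 1, stats::sd) > 0, , drop = FALSE]
        model <- adjacency_tom(ex, config$soft_power,
                               type = config$adjacency_type)
        ms <- detect_modules(model, ex,
                             min_module_size = config$min_module_size,
                             label_prefix = toupper(substr(org, 1, 1)))
        module_sets[[org]] <- list(set = ms, expr = ex, samples = sel)
        if (length(ms$modules)) {
          mt <- module_trait_correlation(
            ms$eigengenes,
            trait_by_sample[sel, c("CHILLING", "LOD"), drop = FALSE])
          files <- c(files, write_table_tsv(
            mt, out(sprintf("module_trait_%s.tsv", org))))
        }
        files <- c(files, write_table_tsv(
          data.frame(gene_id = names(ms$module_of_gene),
                     module = unname(ms$module_of_gene)),
          out(sprintf("modules_%s.tsv", org))))
      }
    }

    if ("graph" %in% config$stages) {
      stage <- "graph"
      for (org in names(module_sets)) {
        ms <- module_sets[[org]]
        assigned <- names(ms$set$module_of_gene)[ms$set$module_of_gene != "grey"]
        if (length(assigned) < 2) next
        corr <- pairwise_correlation(ms$expr[assigned, , drop = FALSE])
        g <- build_topk_graph(corr, config$graph_k, config$graph_r_min)
        files <- c(files, write_table_tsv(
          g$edges, out(sprintf("graph_edges_%s.tsv", org))))
        files <- c(files, write_table_tsv(
          degree_bins(g), out(sprintf("graph_degree_%s.tsv", org))))
      }
    }

    if ("grn" %in% config$stages) {
      stage <- "grn"
      regs <- intersect(config$regulators, rownames(logcpm))
      if (length(regs) >= 2) {
        grn_cfg <- config$grn
        grn_cfg$seed <- derive_seed(config$seed, 6L)
        edges_all <- list()
        for (org in unique(meta$organ)) {
          sel <- meta$organ == org
          w <- genie3_importances(logcpm[, sel, drop = FALSE], regs, grn_cfg)
          ctx <- if (org %in% names(grn_cfg$thresholds)) org else "shared"
          edges_all[[org]] <- threshold_edges(w, ctx, grn_cfg)
        }
        edges <- annotate_dimers(do.call(rbind, edges_all))
        files <- c(files, write_table_tsv(edges, out("grn_edges.tsv")))
      }
    }

    stage <- "manifest"
    manifest <- as.list(tools::md5sum(sort(unique(files))))
    names(manifest) <- basename(sort(unique(files)))
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
  }, error = function(e) {
    marker <- file.path(config$outdir, ".partial")
    writeLines(sprintf("pipeline failed in stage '%s': %s",
                       stage, conditionMessage(e)), marker)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

serialize_config <- function(config) {
  # outdir is implicit in the file location and excluded so that the same
  # analysis in two directories yields identical manifests
  cfg <- unclass(config)
  cfg$outdir <- NULL
  lapply(cfg, function(x) {
    if (inherits(x, "simulation_config") || inherits(x, "grn_params")) {
      unclass(x)
    } else {
      x
    }
  })
}

#' Validate pipeline inputs
#'
#' Checks matrix/metadata sample alignment, gene-id uniqueness and trait
#' coverage; returns a structured report rather than failing.
#'
#' @param counts Count matrix, genes x samples.
#' @param metadata Sample metadata data.frame with a `sample_id` column.
#' @return List with `failures` (character vector, empty when clean) and
#'   `n_genes`, `n_samples`.
#' @export
validate_inputs <- function(counts, metadata) {
  fails <- character(0)
  if (!is.matrix(counts)) fails <- c(fails, "counts is not a matrix")
  if (is.matrix(counts) && anyDuplicated(rownames(counts))) {
    fails <- c(fails, "duplicated gene ids in counts")
  }
  if (is.matrix(counts) && any(counts < 0)) {
    fails <- c(fails, "negative counts")
  }
  if (!"sample_id" %in% names(metadata)) {
    fails <- c(fails, "metadata lacks sample_id")
  } else {
    if (anyDuplicated(metadata$sample_id)) {
      fails <- c(fails, "duplicated sample ids in metadata")
    }
    if (is.matrix(counts) &&
        !identical(sort(colnames(counts)), sort(metadata$sample_id))) {
      fails <- c(fails, "counts columns and metadata sample ids misaligned")
    }
  }
  if (!"timepoint" %in% names(metadata)) {
    fails <- c(fails, "metadata lacks timepoint")
  }
  list(failures = fails,
       n_genes = if (is.matrix(counts)) nrow(counts) else NA_integer_,
       n_samples = if (is.matrix(counts)) ncol(counts) else NA_integer_)
}
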