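# End-to-end orchestration: ties QC, CNV clustering/scoring, marker
# selection, metabolic intersection, reversal-pair mining, the diagnostic
# grid and the prognostic stage into one seeded, manifest-producing run.
# The synthetic mode generates every input with the package's generators,
# so the full workflow runs without external data.

#' Default pipeline configuration
#'
#' Thresholds default to the documented values used throughout the package
#' (REO threshold 0.9; QC mito < 0.10, hemoglobin < 0.03, genes in
#' \[200, 8000\]; AUCell top fraction 0.05; ssGSEA exponent 0.25; marker
#' alpha 0.05 / lfc 0.25).  A single top-level `seed` fans out to per-stage
#' seeds via a stage-name hash, so any stage can be rerun in isolation
#' reproducibly.
#'
#' @param seed mandatory integer run seed.
#' @param outdir output directory for all artifacts.
#' @param ... overrides for any default entry (see the returned list).
#' @return named configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, outdir = tempfile("reopair_run_"), ...) {
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  cfg <- list(
    seed = seed, outdir = outdir,
    reo_threshold = 0.9,
    qc = list(mito_max = 0.10, hb_max = 0.03, min_genes = 200L, max_genes = 8000L),
    aucell_top_fraction = 0.05, ssgsea_alpha = 0.25,
    marker_alpha = 0.05, marker_min_lfc = 0.25,
    model_universe = MODEL_UNIVERSE, grid_mode = "classifiers", cv_folds = 5L,
    k_max = 6L, kmeans_restarts = 10L,
    synthetic = list(
      expr = list(n_genes = 120L, n_tumor = 100L, n_normal = 100L,
                  n_planted_pairs = 6L, reversal_strength = 0.98),
      validation = list(n_tumor = 80L, n_normal = 80L, n_cohorts = 2L),
      cnv = list(n_genes = 150L, n_cells_per_cluster = c(60L, 60L, 60L),
                 amplitudes = c(0.8, 0.9, 1.0), segment_length = 30L,
                 noise_sd = 0.02, n_reference_cells = 40L),
      pathway = list(n_cells = 150L, n_genes = 300L, set_size = 25L,
                     effect = 3, frac_active = 0.5),
      survival = list(beta = 0.7, baseline_rate = 0.1, censor_rate = 0.04)))
  over <- list(...)
  cfg <- modifyList(cfg, over)
  check_flag(cfg$reo_threshold >= 0.5 && cfg$reo_threshold < 1,
             "configuration error: 'reo_threshold' out of range")
  new_tag(cfg, "pipeline_config")
}

# Synthetic count matrix for the QC stage: Poisson counts with designated
# mitochondrial (MT-) and hemoglobin (HBB-) genes, plus a few cells pushed
# over each QC limit so the filter always has work to do.
gen_qc_counts <- function(n_cells = 60L, n_genes = 500L, seed = 1L) {
  genes <- c(sprintf("MT-%d", 1:10), sprintf("HBB-%d", 1:5),
             sprintf("g%04d", seq_len(n_genes - 15L)))
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * n_cells, lambda = 2), n_genes, n_cells)
    counts[1:10, 1:2] <- counts[1:10, 1:2] + 200L        # high-mito cells
    counts[11:15, 3:4] <- counts[11:15, 3:4] + 200L      # high-hemoglobin cells
    counts[, 5] <- 0L; counts[1:50, 5] <- 1L             # too few detected genes
  })
  dimnames(counts) <- list(genes, sprintf("cell%03d", seq_len(n_cells)))
  list(counts = counts, mito_genes = genes[1:10], hb_genes = genes[11:15])
}

write_tsv_artifact <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1L)) & !vapply(df, is.integer, logical(1L))
  for (j in which(num)) df[[j]] <- format_num(df[[j]])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Executes the stages in workflow order — `qc`, `cnv`, `markers`, `pairs`,
#' `diagnose`, `prognose` — on inputs generated by the package's synthetic
#' module, writing every intermediate artifact as TSV under
#' `config$outdir` and returning a manifest with per-file MD5 checksums.
#' Identical config + seed gives identical checksums.
#'
#' The stages mirror the intended use on real cohorts: QC-filter cells;
#' cluster CNV profiles and nominate the most aberrant cluster; select that
#' cluster's markers and intersect them with metabolic gene sets; mine
#' stable reversal pairs from labeled bulk expression restricted to those
#' candidates; binarize and run the diagnostic model grid on training plus
#' validation cohorts; fit Cox models on the pair genes, stratify at the
#' median risk score and compare the groups by log-rank.
#'
#' @param config a [pipeline_config()].
#' @return manifest list: `stages` (per-stage summaries), `files` (path ->
#'   md5 checksum), `seed`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  check_flag(inherits(config, "pipeline_config"),
             "configuration error: 'config' must come from pipeline_config()")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(); files <- character()
  emit <- function(df, name) {
    p <- write_tsv_artifact(df, file.path(config$outdir, name))
    files[[name]] <<- unname(tools::md5sum(p))
  }
  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    stages[[name]] <<- res
  }
  syn <- config$synthetic

  run_stage("qc", function() {
    qc_in <- gen_qc_counts(seed = derive_seed(config$seed, "qc"))
    rep <- qc_filter(qc_in$counts, qc_in$mito_genes, qc_in$hb_genes,
                     mito_max = config$qc$mito_max, hb_max = config$qc$hb_max,
                     min_genes = config$qc$min_genes, max_genes = config$qc$max_genes)
    emit(rep, "qc_report.tsv")
    list(n_cells = nrow(rep), n_kept = sum(rep$keep))
  })

  run_stage("cnv", function() {
    cnv_cfg <- do.call(synthetic_cnv_config,
                       c(syn$cnv, list(seed = derive_seed(config$seed, "cnv"))))
    cnv <- gen_cnv_matrix(cnv_cfg)
    cl <- kmeans_select_k(cnv, k_max = config$k_max,
                          n_restarts = config$kmeans_restarts,
                          seed = derive_seed(config$seed, "cnv_kmeans"))
    emit(data.frame(cell = colnames(cnv$values)[cnv$cell_origin == "tumor"],
                    cluster = cl$assignment), "cnv_assignment.tsv")
    emit(data.frame(k = seq_along(cl$wss), wss = cl$wss, bss = cl$bss),
         "cnv_elbow.tsv")
    emit(data.frame(cluster = names(cl$scores), score = unname(cl$scores)),
         "cnv_scores.tsv")
    list(k = cl$k, nominated = cl$nominated)
  })

  run_stage("markers", function() {
    pw <- syn$pathway
    seed_m <- derive_seed(config$seed, "markers")
    genes <- sprintf("g%04d", seq_len(pw$n_genes))
    set <- sprintf("g%04d", seq_len(pw$set_size))
    cells <- gen_pathway_cells(pw$n_cells, pw$n_genes, set, effect = pw$effect,
                               frac_active = pw$frac_active, seed = seed_m)
    clusters <- ifelse(cells$active, "malignant", "other")
    mk <- select_cluster_markers(cells$values, clusters, "malignant",
                                 min_lfc = config$marker_min_lfc,
                                 alpha = config$marker_alpha)
    collection <- gene_set_collection(
      list(planted_metabolic = set,
           decoy_metabolic = genes[seq(pw$set_size + 1L, pw$set_size + 40L)]),
      source = "synthetic")
    candidates <- intersect_with_metabolic(mk, collection)
    act <- score_all(cells$values, collection, method = "aucell",
                     top_fraction = config$aucell_top_fraction, seed = seed_m)
    emit(mk, "markers.tsv")
    emit(activity_by_cluster(act, clusters), "pathway_activity_by_cluster.tsv")
    list(n_markers = nrow(mk), n_candidates = length(candidates))
  })

  expr_cfg <- do.call(synthetic_expr_config,
                      c(syn$expr, list(seed = derive_seed(config$seed, "pairs"))))
  train <- gen_labeled_expression(expr_cfg)

  run_stage("pairs", function() {
    pairs <- find_reversal_pairs(train, threshold = config$reo_threshold)
    check_flag(nrow(pairs) > 0, "no reversal pairs found")
    write_pairs(pairs, file.path(config$outdir, "reversal_pairs.tsv"))
    files[["reversal_pairs.tsv"]] <<-
      unname(tools::md5sum(file.path(config$outdir, "reversal_pairs.tsv")))
    list(n_pairs = nrow(pairs))
  })
  pairs <- read_pairs(file.path(config$outdir, "reversal_pairs.tsv"))

  run_stage("diagnose", function() {
    cohorts <- lapply(seq_len(syn$validation$n_cohorts), function(i) {
      vc <- unclass(expr_cfg)
      vc$n_tumor <- syn$validation$n_tumor
      vc$n_normal <- syn$validation$n_normal
      vc$seed <- derive_seed(config$seed, paste0("cohort", i))
      ve <- gen_labeled_expression(do.call(synthetic_expr_config, vc))
      list(profile = binarize(ve, pairs), labels = ve$label)
    })
    names(cohorts) <- sprintf("validation%d", seq_along(cohorts))
    grid <- run_model_grid(binarize(train, pairs), train$label, cohorts,
                           universe = config$model_universe, mode = config$grid_mode,
                           cv_folds = config$cv_folds,
                           seed = derive_seed(config$seed, "diagnose"))
    emit(grid, "model_grid.tsv")
    list(n_combos = nrow(grid), top = grid$name[1L], top_mean_auc = grid$mean_auc[1L])
  })

  run_stage("prognose", function() {
    genes <- unique(c(pairs$gene_i, pairs$gene_j))
    tum <- train$values[genes, train$label == "tumor", drop = FALSE]
    surv_cfg <- synthetic_survival_config(
      n_samples = ncol(tum),
      betas = setNames(syn$survival$beta, genes[1L]),
      baseline_rate = syn$survival$baseline_rate,
      censor_rate = syn$survival$censor_rate,
      seed = derive_seed(config$seed, "prognose"))
    surv <- gen_survival(surv_cfg, tum)
    fit <- fit_cox(tum, surv, mode = "multivariate")
    groups <- risk_stratify(fit)
    lr <- km_logrank(groups, surv)
    emit(fit$table, "cox_multivariate.tsv")
    emit(data.frame(sample = surv$sample, group = unname(groups)), "risk_groups.tsv")
    emit(lr$curves, "km_curves.tsv")
    emit(as.data.frame(coexpression(tum[seq_len(min(9L, nrow(tum))), , drop = FALSE])),
         "coexpression.tsv")
    list(c_index = fit$c_index, logrank_p = lr$p_value)
  })

  manifest <- list(stages = stages, files = files, seed = config$seed,
                   config_hash = unname(tools::md5sum(
                     write_tsv_artifact(
                       data.frame(key = "seed", value = as.character(config$seed)),
                       file.path(config$outdir, "config_echo.tsv")))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
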