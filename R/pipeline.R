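#' Pipeline configuration
#'
#' One flat key/value record of every tunable parameter in the pipeline, so
#' a run is fully described by the resolved copy written to its output
#' directory. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed below.
#' @return A `pipeline_config` list.
#' @details Defaults: synthetic stage on with [sim_config()] /
#'   [fixation_model()] defaults; `min_genes = 100` (desk-scale synthetic
#'   fixture; real full-length data typically uses 4000); dropout thresholds
#'   `0, 1, 5, 10, 30, 100` TPM; 16 length bins for abundance comparisons,
#'   10 for coverage, 5 per axis for the threshold sweep; `top_n = 500`
#'   loading transcripts; window `W = 500`; integrity grid 10 x 10 with
#'   `eps = 0.01`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # stage toggles
    run_simulate = TRUE, run_qc = TRUE, run_pca = TRUE, run_stats = TRUE,
    run_coverage = TRUE, run_endbias = TRUE,
    # inputs (used when run_simulate = FALSE)
    catalog_path = NULL, counts_path = NULL, cell_data_path = NULL,
    depth_live_path = NULL, depth_fixed_path = NULL,
    # simulation
    n_transcripts = 2000, n_cells = 50, n_cell_types = 2,
    molecules_per_cell = 20000, reads_per_cell = 2000, read_length = 100,
    d0 = 1500, lambda0 = 2e-4, gamma = 4, pi_live = 0.15, pi_fixed = 0.10,
    full_length_required = TRUE, write_fasta = FALSE,
    # analysis parameters
    min_genes = 100, thresholds = c(0, 1, 5, 10, 30, 100),
    k_length_groups = 16, k_coverage_groups = 10, k_sweep_bins = 5,
    top_n = 500, W = 500, k_grid = 10, eps = 0.01, coverage_bin_width = 50,
    seed = 1L
  )
  over <- list(...)
  if (anyDuplicated(names(over)) > 0) {
    stop("duplicate config key(s): ",
         paste(unique(names(over)[duplicated(names(over))]), collapse = ", "))
  }
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` the config.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the fixation-diagnostic pipeline end to end
#'
#' Executes the stages in dependency order — synthetic data generation,
#' normalization/QC, PCA with cycle removal, loading/dropout statistics,
#' coverage diagnostics, end-bias emulation — writing all tables, a resolved
#' copy of the configuration and a machine-readable `summary.json` naming
#' every artifact and the analysis it belongs to. A stage failure aborts
#' with the failing stage named; artifacts already written are retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary, invisibly: list of per-stage artifact paths and
#'   headline statistics.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.json"))
  summary <- list(seed = config$seed, stages = list())
  artifacts <- list()
  note <- function(stage, analysis, path) {
    artifacts[[length(artifacts) + 1]] <<- list(
      stage = stage, analysis = analysis, path = basename(path))
  }
  stage <- "simulate"
  res <- tryCatch({
    scfg <- sim_config(
      n_transcripts = config$n_transcripts, n_cells = config$n_cells,
      n_cell_types = config$n_cell_types,
      molecules_per_cell = config$molecules_per_cell,
      reads_per_cell = config$reads_per_cell,
      read_length = config$read_length, seed = config$seed
    )
    model <- fixation_model(
      d0 = config$d0, lambda0 = config$lambda0, gamma = config$gamma,
      pi_live = config$pi_live, pi_fixed = config$pi_fixed,
      full_length_required = config$full_length_required
    )
    if (config$run_simulate) {
      catalog <- simulate_catalog(scfg, sequences = config$write_fasta)
      if (config$write_fasta) {
        write_catalog_fasta(catalog, file.path(out_dir, "transcriptome.fa"))
        note(stage, "synthetic transcriptome", "transcriptome.fa")
      }
      sim <- simulate_experiment(catalog, scfg, model)
      counts <- sim$counts
      cell_data <- sim$cell_data
      molecules <- sim$molecules
      depth <- list(
        live = simulate_depth(molecules$live, catalog, scfg,
                              seed = scfg$seed + 4L),
        fixed = simulate_depth(molecules$fixed, catalog, scfg,
                               seed = scfg$seed + 5L)
      )
      note(stage, "counts matrix",
           write_tsv(data.frame(feature_id = rownames(counts), counts,
                                check.names = FALSE),
                     out_dir, "counts.tsv"))
      note(stage, "cell metadata",
           write_tsv(cell_data, out_dir, "cell_data.tsv"))
      note(stage, "catalog", write_catalog(catalog,
                                           file.path(out_dir, "catalog.tsv")))
      note(stage, "depth live",
           write_depth(depth$live, file.path(out_dir, "depth_live.tsv")))
      note(stage, "depth fixed",
           write_depth(depth$fixed, file.path(out_dir, "depth_fixed.tsv")))
    } else {
      catalog <- read_catalog(config$catalog_path)
      counts <- read_matrix_tsv(config$counts_path)
      cell_data <- utils::read.table(config$cell_data_path, header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE)
      molecules <- NULL
      depth <- NULL
      if (!is.null(config$depth_live_path)) {
        depth <- list(live = load_depth(config$depth_live_path, catalog),
                      fixed = load_depth(config$depth_fixed_path, catalog))
      }
    }
    list(catalog = catalog, counts = counts, cell_data = cell_data,
         molecules = molecules, depth = depth, scfg = scfg, model = model)
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  catalog <- res$catalog

  stage <- "qc"
  em <- NULL
  if (config$run_qc || config$run_pca || config$run_stats ||
      config$run_endbias) {
    em <- tryCatch({
      em <- normalize_log_tpm(res$counts, catalog, cell_data = res$cell_data)
      em <- filter_cells(em, config$min_genes)
      em
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
  }
  if (config$run_qc) {
    tryCatch({
      corr <- correlation_analysis(em)
      note(stage, "pairwise correlation + clustering",
           write_tsv(as.data.frame(corr$r), out_dir, "correlation.tsv"))
      summary$stages$qc <- list(
        n_cells = ncol(em$counts),
        mixing = corr$mixing,
        r_range = range(corr$r[upper.tri(corr$r)])
      )
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
  }

  stage <- "pca"
  pca <- NULL
  if (config$run_pca || config$run_stats) {
    tryCatch({
      pca <- run_pca(em, k = 5)
      cycle_genes <- NULL
      if (config$run_simulate) {
        sim_world <- simulate_world(catalog, res$scfg)
        cycle_genes <- catalog$transcript_id[sim_world$cycle_transcripts]
      }
      scores <- data.frame(cell_id = rownames(pca$scores), pca$scores,
                           check.names = FALSE)
      note(stage, "PCA scores (cell type / cycle / treatment)",
           write_tsv(scores, out_dir, "pca_scores.tsv"))
      if (!is.null(cycle_genes)) {
        em_cc <- remove_cycle_effect(em, cycle_genes)
        pca_cc <- run_pca(em_cc, k = 5)
        note(stage, "PCA scores after cycle removal",
             write_tsv(data.frame(cell_id = rownames(pca_cc$scores),
                                  pca_cc$scores, check.names = FALSE),
                       out_dir, "pca_scores_cycle_removed.tsv"))
      }
      sweep_res <- threshold_sweep_pca(em, catalog,
                                       k_bins = config$k_sweep_bins,
                                       top_n = config$top_n)
      note(stage, "length/GC threshold-sweep PCA",
           write_tsv(sweep_res$summary, out_dir, "threshold_sweep.tsv"))
      summary$stages$pca <- list(
        var_explained = pca$var_explained,
        treatment_pc = align_component(pca, em$cell_data$treatment),
        separation = separation_score(pca, em$cell_data$treatment),
        sweep_separation = sweep_res$summary$separation_pc1
      )
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
  }

  stage <- "stats"
  if (config$run_stats) {
    tryCatch({
      tr_pc <- align_component(pca, em$cell_data$treatment)
      other_pc <- setdiff(1:2, tr_pc)[1]
      if (is.na(other_pc)) other_pc <- if (tr_pc == 1) 2 else 1
      set_tr <- top_loadings(pca, tr_pc, config$top_n)
      set_other <- top_loadings(pca, other_pc, config$top_n)
      note(stage, "treatment-PC loading set",
           write_tsv(set_tr, out_dir, "loadings_treatment_pc.tsv"))
      note(stage, "non-treatment-PC loading set",
           write_tsv(set_other, out_dir, "loadings_other_pc.tsv"))
      tt <- feature_ttest(set_tr, set_other, catalog)
      note(stage, "loading-set length/GC t-tests",
           write_tsv(tt, out_dir, "loading_feature_ttests.tsv"))
      mec <- mean_expression_compare(em, set_tr$feature_id)
      note(stage, "loading-set live-vs-fixed means",
           write_tsv(mec$per_feature, out_dir, "loading_mean_compare.tsv"))
      cv <- cv_vs_mean(em)
      note(stage, "CV vs mean", write_tsv(cv, out_dir, "cv_vs_mean.tsv"))
      sweep_drop <- dropout_threshold_sweep(em, config$thresholds)
      note(stage, "dropout threshold sweep",
           write_tsv(sweep_drop$summary, out_dir, "dropout_sweep.tsv"))
      acc <- abundance_class_compare(em)
      bins16 <- bin_equal_size(catalog, "length", config$k_length_groups)
      per_bin <- do.call(rbind, lapply(
        sort(unique(bins16$bin_index)), function(b) {
          ids <- intersect(bins16$transcript_id[bins16$bin_index == b],
                           rownames(em$counts))
          cmp <- mean_expression_compare(em, ids)
          data.frame(length_bin = b, n = length(ids), above = cmp$above,
                     below = cmp$below, tied = cmp$tied)
        }))
      note(stage, "above/below-diagonal counts per length bin",
           write_tsv(per_bin, out_dir, "length_bin_diagonal_counts.tsv"))
      summary$stages$stats <- list(
        feature_ttest_p = stats::setNames(tt$p, tt$feature),
        dropout = sweep_drop$summary[, c("threshold", "mean_live",
                                         "mean_fixed", "stars")],
        abundance_low = if (!is.null(acc$low))
          c(above = acc$low$above, below = acc$low$below),
        abundance_high = if (!is.null(acc$high))
          c(above = acc$high$above, below = acc$high$below)
      )
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
  }

  stage <- "coverage"
  if (config$run_coverage && !is.null(res$depth)) {
    tryCatch({
      bins <- bin_equal_size(catalog, "length", config$k_coverage_groups)
      prof <- group_coverage_profiles(res$depth, catalog, bins,
                                      bin_width = config$coverage_bin_width)
      note(stage, "coverage profiles by length group",
           write_tsv(prof, out_dir, "coverage_profiles.tsv"))
      diff <- coverage_difference(prof)
      note(stage, "live - fixed coverage difference",
           write_tsv(diff, out_dir, "coverage_difference.tsv"))
      ml <- mapping_integrity(res$depth$live, catalog)
      mf <- mapping_integrity(res$depth$fixed, catalog)
      note(stage, "mapping integrity live",
           write_tsv(ml, out_dir, "integrity_live.tsv"))
      note(stage, "mapping integrity fixed",
           write_tsv(mf, out_dir, "integrity_fixed.tsv"))
      iq <- integrity_quotient_heatmap(ml, mf, catalog,
                                       k_length = config$k_grid,
                                       k_gc = config$k_grid,
                                       eps = config$eps)
      note(stage, "integrity-quotient grid",
           write_tsv(as.data.frame(iq$grid), out_dir,
                     "integrity_quotient_grid.tsv"))
      summary$stages$coverage <- list(
        corner_top = iq$grid[config$k_grid, config$k_grid],
        corner_bottom = iq$grid[1, 1]
      )
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
  }

  stage <- "endbias"
  if (config$run_endbias && !is.null(res$molecules)) {
    tryCatch({
      cells <- em$cell_data
      q3 <- window_quantify(res$molecules, catalog, "three_prime",
                            W = config$W, cell_data = cells)
      q5 <- window_quantify(res$molecules, catalog, "five_prime",
                            W = config$W, cell_data = cells)
      rep <- end_bias_report(em, q3, q5)
      note(stage, "end-bias separation report",
           write_tsv(rep$summary, out_dir, "end_bias.tsv"))
      summary$stages$endbias <- stats::setNames(
        as.list(rep$summary$separation), rep$summary$quantification)
    }, error = function(e) stop("stage '", stage, "' failed: ",
                                conditionMessage(e), call. = FALSE))
  }

  summary$artifacts <- artifacts
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(summary)
}
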