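#' Default pipeline configuration
#'
#' Flat key:value configuration of the end-to-end run: QC filtering,
#' normalization, HVG selection, dissimilarity computation, PAM-BS
#' clustering, silhouette (optionally the iterative cell filter),
#' cluster/sample counting, and differential-abundance testing.
#'
#' @param ... overrides of the defaults.
#' @return a named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # input: either simulate = TRUE, or mtx/barcodes/features (+ metadata)
    simulate = TRUE,
    sim_seed = 1, sim_n_cells = 600, sim_n_genes = 120, sim_k_true = 3,
    sim_marker_log_fold = 3, sim_condition_effect = 0,
    matrix = NULL, barcodes = NULL, features = NULL, metadata = NULL,
    orientation = "genes_as_rows",
    # stages
    qc = FALSE, min_counts = 2500, min_genes = 750, max_mito_frac = 0.25,
    normalization = "rawn",
    n_hvg = NULL, hvg_file = NULL,
    metric = "Pearson", precision = "double", workers = 1,
    k = 3, init = "BUILD", max_iter = 1000,
    filter = FALSE, drop_frac = 0.15, target_frac = 0.60, threshold = 0.7,
    model = "time2", test = "lrt",
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat `key: value` YAML; unknown keys are rejected.
#'
#' @param path configuration file.
#' @return a config list (see [pipeline_config()]).
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

validate_config <- function(cfg) {
  chk <- function(value, allowed, what)
    if (!value %in% allowed)
      stop(sprintf("invalid %s '%s' (allowed: %s)", what, value,
                   paste(allowed, collapse = ", ")), call. = FALSE)
  chk(cfg$normalization, c("rawn", "log1n", "none"), "normalization")
  chk(cfg$metric, c("L1", "L2", "Pearson"), "metric")
  chk(cfg$precision, c("double", "single"), "precision")
  chk(cfg$init, c("BUILD", "LAB"), "init")
  chk(cfg$model, c("time", "time2", "phase"), "model")
  chk(cfg$test, c("lrt", "ql"), "test")
  if (cfg$k < 1) stop("k must be >= 1", call. = FALSE)
  invisible(cfg)
}

log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full clustering and differential-abundance pipeline
#'
#' Executes the workflow qc -> normalize -> hvg -> dissimilarity -> PAM-BS ->
#' silhouette (optional filter) -> cluster/sample counts -> differential
#' abundance, persisting each stage's artifacts under `out_dir` together with
#' a manifest recording the parameters and seed. The configuration is
#' validated before any input is read, and re-running with the same
#' configuration reproduces identical result files.
#'
#' @param cfg a configuration list from [pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the main in-memory results (`pam`,
#'   `silhouette`, `counts`, `da`) and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (isTRUE(cfg$simulate)) {
    log_stage("input", "simulating experiment")
    sim <- simulate_experiment(sim_config(
      n_cells = cfg$sim_n_cells, n_genes = cfg$sim_n_genes,
      k_true = cfg$sim_k_true, marker_log_fold = cfg$sim_marker_log_fold,
      condition_effect = cfg$sim_condition_effect, seed = cfg$sim_seed))
    m <- sim$matrix
    meta <- sim$metadata
  } else {
    log_stage("input", paste("reading", cfg$matrix))
    m <- read_mtx(cfg$matrix, cfg$barcodes, cfg$features,
                  orientation = cfg$orientation)
    meta <- read_sample_metadata(cfg$metadata)
  }

  if (isTRUE(cfg$qc)) {
    m <- qc_filter(m, cfg$min_counts, cfg$min_genes, cfg$max_mito_frac)
    rep <- attr(m, "qc_report")
    log_stage("qc", paste(rep["removed"], "cells removed"))
    writeLines(paste(names(rep), rep, sep = "\t"),
               file.path(out_dir, "qc_report.tsv"))
  }

  raw <- m
  if (!is.null(cfg$hvg_file)) {
    keep <- read_gene_list(cfg$hvg_file)
    m <- filter_genes(m, keep)
  } else if (!is.null(cfg$n_hvg)) {
    keep <- select_hvg(raw, cfg$n_hvg)
    writeLines(keep, file.path(out_dir, "hvg.txt"))
    m <- filter_genes(m, keep)
    log_stage("hvg", paste(length(keep), "genes kept"))
  }

  m <- switch(cfg$normalization,
              rawn = normalize_rawn(m),
              log1n = normalize_log1n(m),
              none = m)

  log_stage("dist", sprintf("metric=%s precision=%s workers=%d",
                            cfg$metric, cfg$precision, cfg$workers))
  D <- compute_dissimilarity(m, metric = cfg$metric,
                             precision = cfg$precision,
                             workers = cfg$workers)
  write_dissimilarity(D, file.path(out_dir, "dissimilarity.dsm"))

  log_stage("pam", sprintf("k=%d init=%s", cfg$k, cfg$init))
  fit <- pam(D, k = cfg$k, init = cfg$init, max_iter = cfg$max_iter,
             seed = cfg$seed)
  ids <- cell_ids(m)
  writeLines(ids[fit$medoids], file.path(out_dir, "medoids.tsv"))

  sil <- silhouette(D, fit$labels)
  labels <- fit$labels
  kept <- seq_len(D$n)
  if (isTRUE(cfg$filter)) {
    flt <- silhouette_filter(D, fit$labels, drop_frac = cfg$drop_frac,
                             target_frac = cfg$target_frac,
                             threshold = cfg$threshold,
                             recluster = list(k = cfg$k, init = cfg$init,
                                              max_iter = cfg$max_iter,
                                              seed = cfg$seed))
    kept <- flt$kept
    labels <- flt$labels
    log_stage("filter", sprintf("%d of %d cells kept (criterion %s)",
                                length(kept), D$n,
                                if (flt$met) "met" else "NOT met"))
    writeLines(ids[kept], file.path(out_dir, "kept_cells.tsv"))
    sil <- silhouette(subset_dissimilarity(D, kept), labels)
  }
  write.table(data.frame(cell_id = ids[kept], cluster = labels, s = sil$s),
              file.path(out_dir, "silhouette.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = ids[kept], cluster = labels),
              file.path(out_dir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tab <- cluster_sample_counts(labels, m$sample_of_cell[kept], meta)
  write.table(cbind(cluster = rownames(tab$counts), as.data.frame(tab$counts)),
              file.path(out_dir, "counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  log_stage("da", sprintf("model=%s test=%s", cfg$model, cfg$test))
  da <- if (cfg$test == "lrt") nb_glm_lrt(tab, design = cfg$model)
        else nb_glm_ql(tab, design = cfg$model)
  write_da_result(da, file.path(out_dir, "da_results.tsv"))

  manifest <- c(sprintf("pamcell %s", as.character(utils::packageVersion("pamcell"))),
                sprintf("date\t%s", format(Sys.Date())),
                vapply(names(cfg), function(k)
                  sprintf("%s\t%s", k, paste(format(cfg[[k]]), collapse = ",")),
                  character(1)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(pam = fit, silhouette = sil, counts = tab, da = da,
                 out_dir = out_dir))
}
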