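#' Reproducible run configuration
#'
#' Collects every tunable of the pipeline in one serializable list. The
#' `"scaled"` preset is the desk-scale benchmark condition (3000 cells,
#' 5000 genes, k in {6,...,30}, 30 restarts, 3 replicates); `"full"`
#' matches the full-scale convention (15000 simulated cells or a
#' 50000-cell subsample, k = 2..200, 200 restarts, 200 replicates).
#'
#' @param scale `"scaled"` (default) or `"full"`.
#' @param ... named overrides of any config entry.
#' @return object of class `"acnmf_config"` (a named list).
#' @export
run_config <- function(scale = c("scaled", "full"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    scale = scale,
    seed = 1L,
    sim = list(n_cells = 3000L, n_genes = 5000L, n_groups = 13L),
    max_cells = 50000L,
    n_hvg = 2000L,
    k_grid = seq(6L, 30L, by = 4L),
    j_grid = c(10L, 20L, 50L),
    n_restarts = 30L,
    n_reps = 3L,
    alpha_split = 0.05,
    alpha_fwer = 0.05,
    h_annotation = 50,
    h_classifier = 100,
    outlier_rate = 0.10,
    bin_size = 50L,
    train_frac = 0.75)
  if (scale == "full") {
    cfg$sim <- list(n_cells = 15000L, n_genes = 5000L, n_groups = 13L)
    cfg$k_grid <- seq(2L, 200L, by = 2L)
    cfg$j_grid <- c(10L, 20L, 30L, 50L, 100L, 150L, 200L)
    cfg$n_restarts <- 200L
    cfg$n_reps <- 200L
  }
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  class(cfg) <- "acnmf_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' The round trip is lossless for all numeric and character entries.
#'
#' @param cfg an [run_config()] object.
#' @param path YAML file.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   configuration.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml drops integer types on some round trips; restore where it matters
  for (nm in c("max_cells", "n_hvg", "n_restarts", "n_reps", "bin_size"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  for (nm in c("k_grid", "j_grid"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.integer(cfg[[nm]])
  class(cfg) <- "acnmf_config"
  cfg
}

#' Run the full pipeline into an artifact directory
#'
#' Simulates (or loads) counts, runs the acNMF fit (scan + finalize),
#' optionally scores marker enrichment and the CNV classifier, and writes
#' all outputs as TSV/JSON plus a manifest recording seeds and input
#' hashes. Inputs on disk are never mutated; each run writes into its own
#' directory.
#'
#' @param cfg an [run_config()] object.
#' @param out_dir output directory (must not already contain a manifest).
#' @param counts optional genes x cells matrix; when `NULL` the benchmark
#'   simulation defined by `cfg$sim` is generated.
#' @param marker_sets optional named list of marker gene sets.
#' @param gene_coords optional gene coordinate data.frame enabling the CNV
#'   feature path.
#' @param verbose print stage progress.
#' @return the fitted `"acnmf"` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg, out_dir, counts = NULL, marker_sets = NULL,
                         gene_coords = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "acnmf_config"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path))
    stop("output directory already holds a run (outputs are write-once)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[acnmf] ", ...)

  stage <- "simulate"
  res <- tryCatch({
    if (is.null(counts) && !is.null(cfg$counts_path)) {
      if (!dir.exists(cfg$counts_path) && !file.exists(cfg$counts_path))
        stop("config field 'counts_path' points to a missing location: ",
             cfg$counts_path)
      counts <- read_counts(cfg$counts_path,
                            format = if (dir.exists(cfg$counts_path))
                              "mtx_dir" else "dense_tsv")
    }
    if (is.null(counts)) {
      say("simulating benchmark counts")
      sim <- simulate_counts(do.call(sim_config,
                                     c(cfg$sim, list(seed = cfg$seed))))
      counts <- sim$counts
    } else {
      sim <- NULL
      validate_counts(counts)
    }

    stage <- "fit"
    say("running acNMF (scan + finalize)")
    fit <- acnmf(counts,
                 k_grid = cfg$k_grid, j_grid = cfg$j_grid,
                 n_hvg = cfg$n_hvg, max_cells = cfg$max_cells,
                 n_restarts = cfg$n_restarts, n_reps = cfg$n_reps,
                 alpha = cfg$alpha_split, seed = cfg$seed)

    stage <- "write"
    wz <- fit$programs$Wz
    write.table(data.frame(gene_id = rownames(wz), wz, check.names = FALSE),
                file.path(out_dir, "program_weights_zscore.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    act <- fit$programs$activities
    write.table(data.frame(program = rownames(act), act,
                           check.names = FALSE),
                file.path(out_dir, "program_activities.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(fit$scan$points, file.path(out_dir, "community_curves.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(chosen_k = fit$chosen_k,
                              chosen_J = fit$chosen_J,
                              n_programs = fit$n_programs),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE)
    export_graph(fit$graph, file.path(out_dir, "split_graph.graphml"))

    if (!is.null(marker_sets)) {
      stage <- "enrich"
      say("scoring marker-set enrichment")
      enr <- enrich_programs(wz, marker_sets)
      write.table(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }

    if (!is.null(gene_coords)) {
      stage <- "cnv_features"
      say("computing genomic-bin features")
      bins <- build_bins(gene_coords, bin_size = cfg$bin_size)
      feat <- cnv_features(counts, bins,
                           reference_cells = colnames(counts))
      write.table(data.frame(cell = rownames(feat), feat,
                             check.names = FALSE),
                  file.path(out_dir, "cnv_features.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("acnmf")),
      r_version = R.version.string,
      seed = cfg$seed,
      config = unclass(cfg),
      counts_hash = digest_matrix(counts),
      chosen_k = fit$chosen_k, chosen_J = fit$chosen_J,
      n_programs = fit$n_programs)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
    fit
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# Cheap content hash (sum-based; enough to detect accidental input drift in
# the manifest without a digest dependency).
digest_matrix <- function(m) {
  x <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  sprintf("dim:%dx%d;sum:%.6g;sumsq:%.6g", nrow(m), ncol(m), sum(x),
          sum(x^2))
}
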