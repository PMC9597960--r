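#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Every default is recorded
#' in the emitted run metadata, and a config written to YAML/JSON and read
#' back runs identically.
#'
#' @param model a `metabolic_model` or a model file path.
#' @param counts an `expr_matrix` or a counts path (see [read_counts()]).
#' @param outdir output directory.
#' @param min_genes_per_cell,min_cells_per_gene QC thresholds
#'   (see [qc_filter()]).
#' @param target_sum normalisation total (see [normalize_total()]).
#' @param denoise_stage `"none"`, `"on_counts"`, or `"on_ras"`.
#' @param denoise list of [diffusion_denoise()] parameters.
#' @param bounds_strategy `"plain"` or `"epsilon"`.
#' @param epsilon epsilon for the epsilon strategy (default 0.01).
#' @param objective_id objective reaction; `NULL` uses the model's.
#' @param uptake_magnitude rich-medium uptake bound (default 1000).
#' @param s_genes,g2m_genes optional cell-cycle signatures.
#' @param cluster list of [cluster_features()] parameters.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(model, counts, outdir,
                            min_genes_per_cell = 2000, min_cells_per_gene = 3,
                            target_sum = 1e6,
                            denoise_stage = c("none", "on_counts", "on_ras"),
                            denoise = list(n_pcs = 20, knn = 15, decay = 2, t = 3),
                            bounds_strategy = c("plain", "epsilon"),
                            epsilon = 0.01,
                            objective_id = NULL,
                            uptake_magnitude = 1000,
                            s_genes = NULL, g2m_genes = NULL,
                            cluster = list(n_pcs_grid = c(5, 10, 15, 20),
                                           resolution_grid = c(0.02, 0.05, 0.1, 0.25, 0.5, 1),
                                           neighbors_k = 30),
                            seed = 0) {
  structure(list(
    model = model, counts = counts, outdir = outdir,
    min_genes_per_cell = min_genes_per_cell, min_cells_per_gene = min_cells_per_gene,
    target_sum = target_sum,
    denoise_stage = match.arg(denoise_stage),
    denoise = denoise,
    bounds_strategy = match.arg(bounds_strategy),
    epsilon = epsilon,
    objective_id = objective_id,
    uptake_magnitude = uptake_magnitude,
    s_genes = s_genes, g2m_genes = g2m_genes,
    cluster = cluster,
    seed = seed
  ), class = "pipeline_config")
}

#' Run the full single-cell flux pipeline
#'
#' Orchestrates: QC filtering, total-count normalisation, optional cell-cycle
#' scoring, denoising at the configured stage, RAS computation, sparsity
#' reports, rich-medium FVA, RAS-derived per-cell bounds, essential-reaction
#' analysis, per-cell FBA, flux-matrix QC, flux clustering, and correlation
#' diagnostics. All artifacts are written under `cfg$outdir` with a manifest
#' of MD5 checksums and a metadata file recording every effective parameter
#' and seed; identical configurations reproduce identical artifacts.
#'
#' A stage failure halts the pipeline with the stage name; artifacts written
#' so far are preserved for debugging.
#'
#' @param cfg a `pipeline_config`.
#' @return Invisibly, a list with the in-memory artifacts (`counts`, `ras`,
#'   `fva`, `bounds`, `essential`, `fluxes`, `clusters`, `diagnostics`) and
#'   `paths` (the manifest).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_scflux(sprintf("pipeline halted at stage '%s': %s", name, conditionMessage(e)),
                  class = "scflux_pipeline_error")
    })
  }
  emit <- function(name, writer) {
    p <- file.path(cfg$outdir, name)
    writer(p)
    paths[[name]] <<- p
    p
  }

  model <- stage("read_model", {
    m <- if (inherits(cfg$model, "metabolic_model")) cfg$model else read_model(cfg$model)
    apply_rich_medium(m, cfg$uptake_magnitude)
  })
  objective <- cfg$objective_id %||% model$objective

  x <- stage("read_counts", {
    if (inherits(cfg$counts, "expr_matrix")) cfg$counts else read_counts(cfg$counts)
  })
  x <- stage("qc_filter", qc_filter(x, cfg$min_genes_per_cell, cfg$min_cells_per_gene))
  x <- stage("normalize", normalize_total(x, cfg$target_sum))
  if (!is.null(cfg$s_genes) && !is.null(cfg$g2m_genes)) {
    x <- stage("cell_cycle", score_cell_cycle(x, cfg$s_genes, cfg$g2m_genes, seed = cfg$seed))
  }
  emit("filtered_normalized_counts.tsv", function(p) {
    utils::write.table(as_dense(x$values), p, sep = "\t", quote = FALSE, col.names = NA)
  })

  ras <- stage("ras", do.call(apply_denoising, c(
    list(model = model, x = x, stage = cfg$denoise_stage, seed = cfg$seed), cfg$denoise)))
  emit("ras_matrix.tsv", function(p) {
    utils::write.table(ras$values, p, sep = "\t", quote = FALSE, col.names = NA)
  })
  emit("ras_drop_report.tsv", function(p) {
    utils::write.table(tibble::tibble(dropped_reaction = ras$dropped), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  fva <- stage("fva", run_fva(model))
  emit("fva.tsv", function(p) {
    utils::write.table(fva, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  essential <- stage("essential", find_essential(model, objective))
  emit("essential_reactions.tsv", function(p) {
    utils::write.table(tibble::tibble(reaction = essential$reactions), p,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  })

  spars <- stage("sparsity", sparsity_report(
    ras, essential_set = intersect(essential$reactions, rownames(ras$values))))
  emit("ras_sparsity.tsv", function(p) write_sparsity_report(spars, p))

  bounds <- stage("bounds", {
    if (cfg$bounds_strategy == "plain") ras_bounds(model, fva, ras)
    else epsilon_bounds(model, fva, ras, cfg$epsilon)
  })
  stage("write_bounds", {
    ps <- write_bounds(bounds, cfg$outdir)
    paths[["bounds_L.tsv"]] <- ps[1]; paths[["bounds_U.tsv"]] <- ps[2]
  })

  fluxes <- stage("fba", build_flux_matrix(model, bounds, objective))
  fluxes_qc <- stage("flux_qc", flux_qc(fluxes, ras, essential))
  emit("flux_matrix.tsv", function(p) {
    utils::write.table(fluxes_qc$values, p, sep = "\t", quote = FALSE, col.names = NA)
  })
  emit("flux_qc_log.tsv", function(p) {
    utils::write.table(attr(fluxes_qc, "removal_log"), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  emit("cell_status.tsv", function(p) {
    utils::write.table(tibble::tibble(cell = names(fluxes$status),
                                      status = fluxes$status,
                                      objective = unname(fluxes$objective_values)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  clusters <- stage("cluster", {
    ccfg <- cfg$cluster
    # after flux QC few cells may remain; keep the graph size feasible
    ccfg$neighbors_k <- min(ccfg$neighbors_k %||% 30, ncol(fluxes_qc$values) - 1)
    do.call(cluster_features, c(list(features = fluxes_qc, seed = cfg$seed), ccfg))
  })
  emit("cluster_labels.tsv", function(p) {
    utils::write.table(tibble::tibble(cell = names(clusters$labels),
                                      cluster = as.character(clusters$labels)),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  diagnostics <- stage("diagnostics", {
    out <- list()
    kept <- colnames(fluxes_qc$values)
    if ("s_score" %in% names(x$obs)) {
      sc <- x$obs[match(kept, x$obs$cell), ]
      out$biomass_vs_s <- cor_spearman(fluxes_qc$objective_values, sc$s_score)
      out$biomass_vs_g2m <- cor_spearman(fluxes_qc$objective_values, sc$g2m_score)
    }
    rk <- ras
    rk$values <- rk$values[, kept, drop = FALSE]
    out$pairwise_ras <- pairwise_spearman(rk)
    out
  })
  if (!is.null(diagnostics$biomass_vs_s)) {
    emit("correlation_diagnostics.tsv", function(p) {
      utils::write.table(dplyr::bind_rows(
        dplyr::mutate(diagnostics$biomass_vs_s, comparison = "objective_vs_s_score"),
        dplyr::mutate(diagnostics$biomass_vs_g2m, comparison = "objective_vs_g2m_score")),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  emit("pairwise_ras_spearman.tsv", function(p) {
    utils::write.table(diagnostics$pairwise_ras, p, sep = "\t", quote = FALSE, row.names = FALSE)
  })

  meta <- list(
    package_version = as.character(utils::packageVersion("scflux")),
    parameters = cfg[setdiff(names(cfg), c("model", "counts", "s_genes", "g2m_genes", "outdir"))],
    objective = objective,
    denoise_stage = cfg$denoise_stage,
    lp_feasibility_tolerance = LP_FEAS_TOL,
    seed = cfg$seed,
    n_cells_in = ncol(x$values),
    n_cells_after_flux_qc = ncol(fluxes_qc$values)
  )
  emit("run_metadata.json", function(p) {
    jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  })

  manifest <- tibble::tibble(artifact = names(paths),
                             md5 = unname(tools::md5sum(unlist(paths))))
  utils::write.table(manifest, file.path(cfg$outdir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(model = model, counts = x, ras = ras, fva = fva, bounds = bounds,
                 essential = essential, fluxes = fluxes, fluxes_qc = fluxes_qc,
                 clusters = clusters, diagnostics = diagnostics, sparsity = spars,
                 manifest = manifest, paths = paths))
}
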