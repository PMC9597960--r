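#' Cluster cells on expression or flux features
#'
#' Standard single-cell recipe with silhouette-driven model selection:
#' features are optionally z-scored (per gene or per reaction), reduced by
#' PCA, a kNN graph is built in PC space, and Leiden community detection is
#' run at each resolution of a grid. For every (`n_pcs`, `resolution`) pair
#' the mean silhouette width in the corresponding PCA space is computed; the
#' pair maximising it is selected (grid points yielding a single cluster get
#' silhouette `-Inf` and are never selected). Ties keep the first grid point
#' in order, so selection is deterministic under a fixed seed.
#'
#' Counts should be log-transformed before clustering
#' ([log_normalize()]); flux features are z-scored but not log-transformed.
#'
#' @param features an `expr_matrix`, `flux_matrix`, or plain
#'   features x cells matrix (flux matrices should be QC'd with
#'   [flux_qc()] first).
#' @param n_pcs_grid integer grid of PCA dimensionalities
#'   (default `c(5, 10, 15, 20)`, capped at the data dimensions).
#' @param resolution_grid positive Leiden resolutions
#'   (default `c(0.1, 0.25, 0.5, 1)`).
#' @param neighbors_k kNN graph size (default 15; must be below the number
#'   of cells).
#' @param feature_scaling z-score features before PCA (default `TRUE`;
#'   zero-variance features are dropped).
#' @param seed RNG seed for the Leiden refinement.
#' @return An object of class `cluster_result`: list with `labels` (named
#'   factor), `n_pcs`, `resolution`, `silhouette`, `grid` (tibble of all grid
#'   points), `embedding` (selected PC scores), `seed`.
#' @export
cluster_features <- function(features,
                             n_pcs_grid = c(5, 10, 15, 20),
                             resolution_grid = c(0.1, 0.25, 0.5, 1),
                             neighbors_k = 15,
                             feature_scaling = TRUE,
                             seed = 0) {
  vals <- if (inherits(features, c("expr_matrix", "flux_matrix", "ras_matrix"))) {
    as_dense(features$values)
  } else {
    as_dense(features)
  }
  stopifnot(length(n_pcs_grid) >= 1, length(resolution_grid) >= 1)
  n_cells <- ncol(vals)
  if (n_cells < neighbors_k + 1) {
    stop_scflux(sprintf("need more than neighbors_k = %d cells, have %d", neighbors_k, n_cells),
                class = "scflux_validation_error")
  }
  X <- t(vals)                                  # cells x features
  if (feature_scaling) {
    sds <- apply(X, 2, stats::sd)
    X <- scale(X[, sds > 0, drop = FALSE])
  }
  max_pcs <- min(max(n_pcs_grid), n_cells - 1, ncol(X))
  pca <- stats::prcomp(X, center = !feature_scaling, scale. = FALSE, rank. = max_pcs)

  grid <- tidyr::expand_grid(n_pcs = pmin(n_pcs_grid, max_pcs), resolution = resolution_grid)
  grid <- dplyr::distinct(grid)
  evals <- lapply(seq_len(nrow(grid)), function(i) {
    k <- grid$n_pcs[i]
    scores <- pca$x[, seq_len(k), drop = FALSE]
    labels <- leiden_knn(scores, neighbors_k, grid$resolution[i], seed)
    sil <- if (length(unique(labels)) > 1) {
      mean(cluster::silhouette(as.integer(labels), stats::dist(scores))[, "sil_width"])
    } else {
      -Inf
    }
    list(labels = labels, silhouette = sil)
  })
  grid$silhouette <- vapply(evals, `[[`, 0, "silhouette")
  grid$n_clusters <- vapply(evals, function(e) length(unique(e$labels)), 0L)
  if (all(!is.finite(grid$silhouette))) {
    warn_scflux("every grid point produced a single cluster (no separable structure)",
                class = "scflux_cluster_warning")
  }
  best <- which.max(grid$silhouette)   # first maximum in grid order
  labels <- factor(evals[[best]]$labels)
  names(labels) <- colnames(vals)
  structure(list(
    labels = labels,
    n_pcs = grid$n_pcs[best],
    resolution = grid$resolution[best],
    silhouette = grid$silhouette[best],
    grid = grid,
    embedding = pca$x[, seq_len(grid$n_pcs[best]), drop = FALSE],
    seed = seed
  ), class = "cluster_result")
}

# kNN graph in PC space + Leiden (modularity objective), seeded.
leiden_knn <- function(scores, k, resolution, seed) {
  n <- nrow(scores)
  D <- as.matrix(stats::dist(scores))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[2:(k + 1)]
    cbind(i, nb)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- with_seed(seed, igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution, n_iterations = 3))
  igraph::membership(comm)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cells in %d clusters (n_pcs = %d, resolution = %g, silhouette = %.3f)\n",
              length(x$labels), nlevels(x$labels), x$n_pcs, x$resolution, x$silhouette))
  invisible(x)
}

#' Spearman correlation diagnostics
#'
#' Tie-corrected Spearman rank correlation between two equal-length vectors
#' (e.g. a reaction's RAS profile and a cell-cycle score, or the biomass
#' optimum and the S score). A constant vector makes the correlation
#' undefined: `rho` is returned as `NA` with `defined = FALSE`.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `defined`.
#' @export
cor_spearman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop_scflux("cor_spearman needs two equal-length vectors of length >= 3",
                class = "scflux_validation_error")
  }
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = length(a), defined = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a), defined = TRUE)
}

#' Distribution of pairwise Spearman correlations between rows
#'
#' Computes the Spearman correlation of every unordered pair of rows of a
#' matrix (e.g. all reaction pairs of a RAS matrix) and returns the
#' off-diagonal distribution.
#'
#' @param m a `ras_matrix`, `flux_matrix`, `expr_matrix`, or plain matrix;
#'   constant rows are skipped.
#' @return Tibble with `row_a`, `row_b`, `rho`.
#' @export
pairwise_spearman <- function(m) {
  vals <- if (inherits(m, c("expr_matrix", "ras_matrix", "flux_matrix"))) {
    as_dense(m$values)
  } else {
    as_dense(m)
  }
  keep <- apply(vals, 1, stats::sd) > 0
  vals <- vals[keep, , drop = FALSE]
  cm <- stats::cor(t(vals), method = "spearman")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  tibble::tibble(row_a = rownames(cm)[idx[, 1]],
                 row_b = rownames(cm)[idx[, 2]],
                 rho = cm[idx])
}

#' Agreement between a clustering and known groups
#'
#' Chance-adjusted Rand index and normalised mutual information between the
#' cluster labels and an a priori grouping. Both metrics are invariant to
#' label permutation.
#'
#' @param result a `cluster_result` or a label vector.
#' @param known vector of known group labels, aligned to the cells (same
#'   length and order).
#' @return A one-row tibble: `ari`, `nmi`, `n`.
#' @export
compare_to_known_groups <- function(result, known) {
  labels <- if (inherits(result, "cluster_result")) result$labels else result
  if (length(labels) != length(known)) {
    stop_scflux(sprintf("label lengths differ: %d vs %d", length(labels), length(known)),
                class = "scflux_validation_error")
  }
  la <- as.integer(factor(labels))
  lb <- as.integer(factor(known))
  tibble::tibble(
    ari = mclust::adjustedRandIndex(la, lb),
    nmi = igraph::compare(la, lb, method = "nmi"),
    n = length(la)
  )
}
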