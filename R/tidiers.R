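#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an expression matrix into long format
#'
#' @param x an `expr_matrix`.
#' @param ... unused.
#' @return Tibble with `gene`, `cell`, `value`, `layer`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  m <- as_dense(x$values)
  tibble::tibble(
    gene = rep(rownames(m), times = ncol(m)),
    cell = rep(colnames(m), each = nrow(m)),
    value = as.numeric(m),
    layer = x$layer
  )
}

#' Tidy a RAS matrix into long format
#'
#' @param x a `ras_matrix`.
#' @param ... unused.
#' @return Tibble with `reaction`, `cell`, `ras`.
#' @export
tidy.ras_matrix <- function(x, ...) {
  m <- x$values
  tibble::tibble(
    reaction = rep(rownames(m), times = ncol(m)),
    cell = rep(colnames(m), each = nrow(m)),
    ras = as.numeric(m)
  )
}

#' One-row summary of a RAS matrix
#'
#' @param x a `ras_matrix`.
#' @param ... unused.
#' @return Tibble with `n_reactions`, `n_cells`, `coverage`, `n_dropped`,
#'   `zero_fraction`, `layer`.
#' @export
glance.ras_matrix <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$values), n_cells = ncol(x$values),
    coverage = x$coverage, n_dropped = length(x$dropped),
    zero_fraction = zero_fraction(x$values), layer = x$layer
  )
}

#' Tidy a flux matrix into long format
#'
#' @param x a `flux_matrix`.
#' @param ... unused.
#' @return Tibble with `reaction`, `cell`, `flux`.
#' @export
tidy.flux_matrix <- function(x, ...) {
  m <- x$values
  tibble::tibble(
    reaction = rep(rownames(m), times = ncol(m)),
    cell = rep(colnames(m), each = nrow(m)),
    flux = as.numeric(m)
  )
}

#' One-row summary of a flux matrix
#'
#' @param x a `flux_matrix`.
#' @param ... unused.
#' @return Tibble with `n_reactions`, `n_cells`, `n_optimal`,
#'   `n_infeasible`, `objective_id`, `mean_objective`.
#' @export
glance.flux_matrix <- function(x, ...) {
  tibble::tibble(
    n_reactions = nrow(x$values), n_cells = ncol(x$values),
    n_optimal = sum(x$status == "optimal"),
    n_infeasible = sum(x$status != "optimal"),
    objective_id = x$objective_id,
    mean_objective = mean(x$objective_values, na.rm = TRUE)
  )
}

#' Tidy cluster labels
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return Tibble with `cell`, `cluster` and the first two embedding
#'   coordinates.
#' @export
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(
    cell = names(x$labels),
    cluster = as.character(x$labels),
    pc1 = x$embedding[, 1],
    pc2 = if (ncol(x$embedding) > 1) x$embedding[, 2] else 0
  )
}

#' One-row summary of a clustering
#'
#' @param x a `cluster_result`.
#' @param ... unused.
#' @return Tibble with the selected hyper-parameters and silhouette.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$labels), n_clusters = nlevels(x$labels),
    n_pcs = x$n_pcs, resolution = x$resolution,
    silhouette = x$silhouette, seed = x$seed
  )
}

#' Tidy a sparsity report
#'
#' @param x a `sparsity_report`.
#' @param ... unused.
#' @return The per-cell tibble (`cell`, `zero_fraction`, optionally
#'   `essential_zero_fraction` and `group`).
#' @export
tidy.sparsity_report <- function(x, ...) x$per_cell

#' One-row summary of a sparsity report
#'
#' @param x a `sparsity_report`.
#' @param ... unused.
#' @return Tibble with `overall` and `essential_overall` zero fractions.
#' @export
glance.sparsity_report <- function(x, ...) {
  tibble::tibble(overall = x$overall, essential_overall = x$essential_overall)
}
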