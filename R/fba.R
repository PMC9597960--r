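#' Reactions essential for an objective
#'
#' A reaction is essential for an objective flux when restricting its bounds
#' to (0, 0) drives the maximal objective to zero. Essentiality is computed
#' once on the medium-applied model (not per cell): every candidate reaction
#' is knocked out in turn, the FBA maximum re-solved, and the original
#' bounds restored.
#'
#' @param model a `metabolic_model` with a feasible, strictly positive
#'   baseline optimum for the objective.
#' @param objective_id objective reaction (defaults to the model's).
#' @param zero_tol absolute tolerance below which an optimum counts as zero
#'   (default `1e-9`).
#' @return An object of class `essential_set`: list with `objective`,
#'   `reactions` (the essential ids) and `baseline` (the unperturbed
#'   optimum).
#' @export
find_essential <- function(model, objective_id = model$objective, zero_tol = 1e-9) {
  cvec <- objective_cvec(model, objective_id)
  base <- solve_flux_lp(model$S, model$lower_bounds, model$upper_bounds, cvec)
  if (base$status != "optimal" || base$objval <= zero_tol) {
    stop_scflux("baseline objective optimum is zero or infeasible; essentiality is undefined",
                class = "scflux_infeasible_error")
  }
  ess <- vapply(seq_along(model$reactions), function(j) {
    lb <- model$lower_bounds; ub <- model$upper_bounds
    lb[j] <- 0; ub[j] <- 0
    ko <- solve_flux_lp(model$S, lb, ub, cvec)
    ko$status != "optimal" || ko$objval <= zero_tol
  }, logical(1))
  structure(list(objective = objective_id,
                 reactions = model$reactions[ess],
                 baseline = base$objval),
            class = "essential_set")
}

#' @export
print.essential_set <- function(x, ...) {
  cat(sprintf("<essential_set> %d reactions essential for %s (baseline optimum %.4g)\n",
              length(x$reactions), x$objective, x$baseline))
  invisible(x)
}

#' Solve one cell's flux balance analysis problem
#'
#' Maximises the objective flux subject to the steady-state constraint and
#' the cell's RAS-derived bounds, then applies a parsimonious tiebreak
#' (minimise total absolute flux at the fixed optimum) so the reported
#' vector is a unique, solver-stable optimal vertex.
#'
#' @param model a `metabolic_model`.
#' @param bounds a `cell_bounds` object covering the cell.
#' @param cell cell identifier (a column of the bounds matrices).
#' @param objective_id objective reaction (defaults to the model's).
#' @return List with `status` (`"optimal"` or `"infeasible"`), `objective`
#'   (the optimum, `NA` when infeasible) and `fluxes` (named vector).
#'   Infeasible cells are flagged, never an exception.
#' @export
solve_cell_fba <- function(model, bounds, cell, objective_id = model$objective) {
  stopifnot(inherits(bounds, "cell_bounds"))
  if (!cell %in% colnames(bounds$L)) {
    stop_scflux(sprintf("no bounds for cell '%s'", cell), class = "scflux_validation_error")
  }
  lb <- bounds$L[model$reactions, cell]
  ub <- bounds$U[model$reactions, cell]
  cvec <- objective_cvec(model, objective_id)
  opt <- solve_flux_lp(model$S, lb, ub, cvec)
  if (opt$status != "optimal") {
    return(list(status = "infeasible", objective = NA_real_,
                fluxes = stats::setNames(rep(NA_real_, length(cvec)), model$reactions)))
  }
  v <- solve_parsimony_lp(model$S, lb, ub, cvec, opt$objval)
  if (is.null(v)) v <- opt$v  # fall back to the raw optimal vertex
  list(status = "optimal", objective = opt$objval,
       fluxes = stats::setNames(v, model$reactions))
}

#' Assemble the per-cell optimal flux matrix
#'
#' Runs [solve_cell_fba()] for every cell in the bounds set and collects the
#' optimal flux vectors into a reactions x cells matrix — the feature space
#' for flux-based clustering. Per-cell solver statuses and objective optima
#' are preserved for downstream quality control.
#'
#' @inheritParams solve_cell_fba
#' @return An object of class `flux_matrix`: list with `values`
#'   (reactions x cells), `objective_values`, `status`, `objective_id`.
#' @export
build_flux_matrix <- function(model, bounds, objective_id = model$objective) {
  cells <- colnames(bounds$L)
  sol <- lapply(cells, function(cl) solve_cell_fba(model, bounds, cl, objective_id))
  values <- vapply(sol, function(s) s$fluxes, numeric(length(model$reactions)))
  dimnames(values) <- list(model$reactions, cells)
  structure(list(
    values = values,
    objective_values = stats::setNames(vapply(sol, `[[`, 0, "objective"), cells),
    status = stats::setNames(vapply(sol, `[[`, "", "status"), cells),
    objective_id = objective_id
  ), class = "flux_matrix")
}

#' @export
print.flux_matrix <- function(x, ...) {
  cat(sprintf("<flux_matrix> %d reactions x %d cells, objective %s\n",
              nrow(x$values), ncol(x$values), x$objective_id))
  cat(sprintf("  optimal: %d; infeasible: %d\n",
              sum(x$status == "optimal"), sum(x$status != "optimal")))
  invisible(x)
}

#' @export
dim.flux_matrix <- function(x) dim(x$values)

#' Quality-control the flux matrix on essential reactions
#'
#' Removes every cell whose RAS is zero (within `zero_tol`) for at least one
#' GPR-bearing reaction essential to the objective: such cells cannot carry
#' objective flux under plain RAS bounds, so their optimal flux vector is an
#' artifact of dropout rather than biology. The removal log records, per
#' cell, how many essential reactions had zero RAS.
#'
#' @param fm a `flux_matrix`.
#' @param ras the `ras_matrix` the bounds were derived from.
#' @param essential an `essential_set` for the same objective.
#' @param zero_tol absolute zero tolerance (default `1e-9`).
#' @return The filtered `flux_matrix`, with the removal log as attribute
#'   `removal_log` (tibble: `cell`, `n_zero_essential`, `removed`).
#' @export
flux_qc <- function(fm, ras, essential, zero_tol = 1e-9) {
  stopifnot(inherits(fm, "flux_matrix"), inherits(ras, "ras_matrix"),
            inherits(essential, "essential_set"))
  ess <- intersect(essential$reactions, rownames(ras$values))
  n_zero <- if (length(ess)) {
    colSums(ras$values[ess, , drop = FALSE] <= zero_tol)
  } else {
    stats::setNames(rep(0L, ncol(ras$values)), colnames(ras$values))
  }
  n_zero <- n_zero[colnames(fm$values)]
  removed <- n_zero > 0
  log <- tibble::tibble(cell = colnames(fm$values),
                        n_zero_essential = as.integer(n_zero),
                        removed = unname(removed))
  if (all(removed)) {
    stop_scflux("flux_qc removed every cell: all have a zero RAS on an essential reaction",
                class = "scflux_empty_error")
  }
  keep <- !removed
  out <- fm
  out$values <- fm$values[, keep, drop = FALSE]
  out$objective_values <- fm$objective_values[keep]
  out$status <- fm$status[keep]
  attr(out, "removal_log") <- log
  out
}
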