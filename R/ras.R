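#' Compute the Reaction Activity Score matrix
#'
#' Substitutes per-cell transcript abundances into each reaction's GPR rule
#' (minimum over AND, sum over OR, missing genes dropped from the rule; see
#' [eval_gpr()]). The result has one row per GPR-bearing reaction with at
#' least one of its genes present in the expression matrix; reactions whose
#' genes are all absent are dropped and listed in the drop report.
#'
#' @param model a `metabolic_model`.
#' @param x an `expr_matrix`; a normalized (or denoised) layer is expected
#'   and a raw layer triggers a warning.
#' @return An object of class `ras_matrix`: list with `values`
#'   (reactions x cells), `dropped` (reaction ids with no measured gene),
#'   `coverage` (fraction of model genes present in `x`), and `layer`.
#' @export
compute_ras <- function(model, x) {
  stopifnot(inherits(model, "metabolic_model"), inherits(x, "expr_matrix"))
  if (x$layer == "raw") {
    warn_scflux("computing RAS on raw counts; normalization is recommended",
                class = "scflux_layer_warning")
  }
  gpr_rxns <- model$reactions[nzchar(model$gpr)]
  if (!length(gpr_rxns)) {
    stop_scflux("model has no GPR-bearing reactions", class = "scflux_validation_error")
  }
  m <- as_dense(x$values)
  genes_present <- rownames(m)
  rules <- lapply(model$gpr[gpr_rxns], parse_gpr)
  mg <- sort(unique(unlist(lapply(rules, gpr_genes))))
  coverage <- length(intersect(mg, genes_present)) / length(mg)

  keep <- vapply(rules, function(r) any(gpr_genes(r) %in% genes_present), logical(1))
  dropped <- gpr_rxns[!keep]
  kept <- gpr_rxns[keep]
  if (!length(kept)) {
    stop_scflux("no GPR-bearing reaction has a measured gene",
                class = "scflux_empty_error")
  }
  vals <- vapply(rules[keep], function(r) {
    expr <- lapply(stats::setNames(nm = intersect(gpr_genes(r), genes_present)),
                   function(g) m[g, ])
    eval_gpr(r, expr)
  }, numeric(ncol(m)))
  vals <- if (is.null(dim(vals))) matrix(vals, ncol = 1) else t(vals)
  dimnames(vals) <- list(kept, colnames(m))
  structure(list(values = vals, dropped = dropped, coverage = coverage,
                 layer = x$layer, cells = colnames(m)),
            class = "ras_matrix")
}

#' @export
print.ras_matrix <- function(x, ...) {
  cat(sprintf("<ras_matrix> %d reactions x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  cat(sprintf("  gene coverage: %.1f%%; dropped reactions: %d\n",
              100 * x$coverage, length(x$dropped)))
  invisible(x)
}

#' @export
dim.ras_matrix <- function(x) dim(x$values)

#' Sparsity report for an expression or RAS matrix
#'
#' Computes the overall fraction of exact zeros and the per-cell zero
#' fractions, optionally also restricted to a set of rows of interest (e.g.
#' the reactions essential for the objective).
#'
#' @param m an `expr_matrix`, `ras_matrix`, or plain matrix.
#' @param essential_set optional character vector of row identifiers the
#'   restricted summary uses; identifiers absent from the matrix are an
#'   error.
#' @param groups optional per-cell group labels carried into the per-cell
#'   table (for grouped violin plots).
#' @return An object of class `sparsity_report`: list with `overall`
#'   (fraction in \[0, 1\]), `per_cell` (tibble `cell`, `zero_fraction`,
#'   optional `essential_zero_fraction`, `group`), and
#'   `essential_overall` (or `NA` when no set is given).
#' @export
sparsity_report <- function(m, essential_set = NULL, groups = NULL) {
  vals <- if (inherits(m, c("expr_matrix", "ras_matrix"))) as_dense(m$values) else as_dense(m)
  per_cell <- colSums(vals == 0) / nrow(vals)
  out <- list(
    overall = zero_fraction(vals),
    per_cell = tibble::tibble(cell = colnames(vals) %||% as.character(seq_len(ncol(vals))),
                              zero_fraction = unname(per_cell)),
    essential_overall = NA_real_
  )
  if (!is.null(essential_set)) {
    missing_rows <- setdiff(essential_set, rownames(vals))
    if (length(missing_rows)) {
      stop_scflux(sprintf("essential ids not in the matrix: %s",
                          paste(missing_rows, collapse = ", ")),
                  class = "scflux_validation_error")
    }
    ev <- vals[essential_set, , drop = FALSE]
    out$essential_overall <- zero_fraction(ev)
    out$per_cell$essential_zero_fraction <- unname(colSums(ev == 0) / nrow(ev))
  }
  if (!is.null(groups)) out$per_cell$group <- groups
  structure(out, class = "sparsity_report")
}

#' @export
print.sparsity_report <- function(x, ...) {
  cat(sprintf("<sparsity_report> overall zero fraction: %.2f%%\n", 100 * x$overall))
  if (!is.na(x$essential_overall)) {
    cat(sprintf("  restricted to essential rows: %.2f%%\n", 100 * x$essential_overall))
  }
  invisible(x)
}

#' Write a sparsity report to TSV
#'
#' @param report a `sparsity_report`.
#' @param path output TSV path; the per-cell table is written with the
#'   overall fractions as a leading comment line.
#' @return `path`, invisibly.
#' @export
write_sparsity_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# overall_zero_fraction=%.10g essential_zero_fraction=%.10g",
                     report$overall, report$essential_overall), con)
  utils::write.table(report$per_cell, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
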