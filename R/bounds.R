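#' Per-cell flux bounds from RAS values (plain strategy)
#'
#' Rescales each GPR-bearing internal reaction's flux-variability envelope
#' by the cell's relative activity:
#' \deqn{U^c_j = F^u_j \frac{RAS^c_j}{\max_c RAS^c_j}, \qquad
#'       L^c_j = F^l_j \frac{RAS^c_j}{\max_c RAS^c_j}.}
#' The maximum is taken over the cells of the current dataset. A reaction
#' whose RAS is zero in every cell keeps bounds (0, 0) for all cells.
#' Reactions without a GPR keep their envelope \eqn{(F^l_j, F^u_j)};
#' exchange reactions keep the medium bounds.
#'
#' @param model a `metabolic_model` (medium applied).
#' @param fva an `fva_result` from [run_fva()] covering all RAS reactions.
#' @param ras a `ras_matrix`.
#' @return An object of class `cell_bounds`: list with `L` and `U`
#'   (reactions x cells matrices over all model reactions), `strategy`,
#'   `epsilon`, and `notes`.
#' @export
ras_bounds <- function(model, fva, ras) {
  build_bounds(model, fva, ras, strategy = "plain", epsilon = 0)
}

#' Per-cell flux bounds with a residual-capacity epsilon
#'
#' Variant of [ras_bounds()] that leaves a small residual capacity
#' \eqn{\epsilon} to reactions with zero RAS, mitigating false zeros:
#' \deqn{U^c_j = \epsilon + (F^u_j - \epsilon)\,\rho^c_j, \qquad
#'       L^c_j = -\epsilon + (F^l_j + \epsilon)\,\rho^c_j,}
#' with \eqn{\rho^c_j = RAS^c_j / \max_c RAS^c_j} (ratio 0 when the maximum
#' is zero). At ratio 0 the bounds are \eqn{(-\epsilon, \epsilon)}; at ratio
#' 1 they telescope back to \eqn{(F^l_j, F^u_j)}; as \eqn{\epsilon \to 0}
#' the plain strategy is recovered. Note the formulas give slightly negative
#' lower bounds to irreversible reactions at sub-maximal RAS; they are
#' applied as written and any inversion \eqn{L > U} (possible when
#' \eqn{\epsilon \ge F^u_j}) is clamped to \eqn{L = U} with a warning and a
#' count in `notes`.
#'
#' @inheritParams ras_bounds
#' @param epsilon positive residual capacity (default 0.01, flux units).
#' @return A `cell_bounds` object with `strategy = "epsilon"`.
#' @export
epsilon_bounds <- function(model, fva, ras, epsilon = 0.01) {
  stopifnot(epsilon > 0)
  build_bounds(model, fva, ras, strategy = "epsilon", epsilon = epsilon)
}

build_bounds <- function(model, fva, ras, strategy, epsilon) {
  stopifnot(inherits(model, "metabolic_model"), inherits(fva, "fva_result"),
            inherits(ras, "ras_matrix"))
  rv <- ras$values
  if (any(rv < 0, na.rm = TRUE)) {
    stop_scflux("negative RAS values", class = "scflux_validation_error")
  }
  missing_fva <- setdiff(rownames(rv), fva$reaction)
  if (length(missing_fva)) {
    stop_scflux(sprintf("FVA result lacks reactions: %s", paste(missing_fva, collapse = ", ")),
                class = "scflux_validation_error")
  }
  cells <- colnames(rv)
  R <- length(model$reactions)
  Fl <- stats::setNames(fva$min[match(model$reactions, fva$reaction)], model$reactions)
  Fu <- stats::setNames(fva$max[match(model$reactions, fva$reaction)], model$reactions)
  # defaults: envelope for non-exchange, medium bounds for exchange
  L0 <- ifelse(model$exchange, model$lower_bounds, Fl)
  U0 <- ifelse(model$exchange, model$upper_bounds, Fu)
  L <- matrix(L0, R, length(cells), dimnames = list(model$reactions, cells))
  U <- matrix(U0, R, length(cells), dimnames = list(model$reactions, cells))

  scaled <- intersect(rownames(rv), model$reactions[nzchar(model$gpr) & !model$exchange])
  rmax <- apply(rv[scaled, , drop = FALSE], 1, max)
  ratio <- rv[scaled, , drop = FALSE] / ifelse(rmax > 0, rmax, 1)
  ratio[rmax == 0, ] <- 0
  if (strategy == "plain") {
    U[scaled, ] <- Fu[scaled] * ratio
    L[scaled, ] <- Fl[scaled] * ratio
  } else {
    U[scaled, ] <- epsilon + (Fu[scaled] - epsilon) * ratio
    L[scaled, ] <- -epsilon + (Fl[scaled] + epsilon) * ratio
  }
  n_clamped <- sum(L > U)
  if (n_clamped > 0) {
    warn_scflux(sprintf(
      "%d bound pairs had L > U (epsilon >= FVA max for some reaction); clamped to L = U",
      n_clamped), class = "scflux_bounds_warning")
    L[L > U] <- U[L > U]
  }
  structure(list(L = L, U = U, strategy = strategy, epsilon = epsilon,
                 notes = tibble::tibble(n_clamped = n_clamped)),
            class = "cell_bounds")
}

#' @export
print.cell_bounds <- function(x, ...) {
  cat(sprintf("<cell_bounds> %d reactions x %d cells, strategy = %s",
              nrow(x$L), ncol(x$L), x$strategy))
  if (x$strategy == "epsilon") cat(sprintf(" (epsilon = %g)", x$epsilon))
  cat("\n")
  invisible(x)
}

#' Write per-cell bounds as a pair of TSV files
#'
#' @param bounds a `cell_bounds` object.
#' @param dir output directory; files `bounds_L.tsv` and `bounds_U.tsv` are
#'   written with reactions in rows and cells in columns.
#' @return The two paths, invisibly.
#' @export
write_bounds <- function(bounds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pl <- file.path(dir, "bounds_L.tsv")
  pu <- file.path(dir, "bounds_U.tsv")
  utils::write.table(bounds$L, pl, sep = "\t", quote = FALSE, col.names = NA)
  utils::write.table(bounds$U, pu, sep = "\t", quote = FALSE, col.names = NA)
  invisible(c(pl, pu))
}
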