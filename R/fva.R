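#' Flux variability analysis
#'
#' For each reaction solves the pair of linear programs
#' \deqn{\max / \min\; v_j \quad \mathrm{s.t.}\quad S v = 0,\; v_L \le v \le v_U,}
#' returning the feasible flux envelope \eqn{[F^l_j, F^u_j]} of every
#' reaction. No fraction-of-optimum constraint is applied: the objective is
#' not fixed, so the envelopes describe the whole steady-state polytope
#' under the current bounds (typically after [apply_rich_medium()]).
#'
#' @param model a `metabolic_model` with the medium applied.
#' @param reactions optional character vector restricting the analysis.
#' @return A tibble of class `fva_result` with columns `reaction`, `min`,
#'   `max`, `status_min`, `status_max`.
#' @export
run_fva <- function(model, reactions = NULL) {
  reactions <- reactions %||% model$reactions
  bad <- setdiff(reactions, model$reactions)
  if (length(bad)) {
    stop_scflux(sprintf("unknown reactions: %s", paste(bad, collapse = ", ")),
                class = "scflux_validation_error")
  }
  base <- solve_flux_lp(model$S, model$lower_bounds, model$upper_bounds,
                        rep(0, length(model$reactions)))
  if (base$status != "optimal") {
    empty <- model$lower_bounds > model$upper_bounds
    diag_msg <- if (any(empty)) {
      sprintf("bound interval empty for: %s",
              paste(model$reactions[empty], collapse = ", "))
    } else {
      "steady-state constraints admit no flux vector within the bounds"
    }
    stop_scflux(paste("base LP infeasible;", diag_msg),
                class = "scflux_infeasible_error")
  }
  rows <- lapply(reactions, function(rj) {
    cvec <- objective_cvec(model, rj)
    up <- solve_flux_lp(model$S, model$lower_bounds, model$upper_bounds, cvec, maximize = TRUE)
    lo <- solve_flux_lp(model$S, model$lower_bounds, model$upper_bounds, cvec, maximize = FALSE)
    tibble::tibble(reaction = rj,
                   min = lo$objval, max = up$objval,
                   status_min = lo$status, status_max = up$status)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fva_result", class(out))
  out
}
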