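## Linear-programming layer.
##
## All flux computations reduce to LPs of the form
##   max/min  c'v   s.t.  S v = 0,  lb <= v <= ub.
## pracma::linprog works on nonnegative variables, so problems are shifted
## (x = v - lb >= 0) with the upper bounds as inequality rows. A parsimony
## variant fixes the objective value and minimises total absolute flux over
## split variables, giving a unique, solver-stable optimal vertex.

LP_FEAS_TOL <- 1e-9

# Solve max/min c'v s.t. S v = 0, lb <= v <= ub.
# Returns list(status = "optimal"|"infeasible"|"error", objval, v).
solve_flux_lp <- function(S, lb, ub, cvec, maximize = TRUE) {
  S <- as_dense(S)
  n <- ncol(S)
  rng <- ub - lb
  beq <- as.numeric(-S %*% lb)
  # the backend consumes RNG internally; pin it so solves are deterministic
  res <- tryCatch(
    with_seed(1L, pracma::linprog(cc = cvec, A = diag(n), b = rng, Aeq = S, beq = beq,
                                  maximize = maximize, maxiter = 100 + 20 * n)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$errno) || res$errno != 1 || anyNA(res$x)) {
    return(list(status = "infeasible", objval = NA_real_, v = rep(NA_real_, n)))
  }
  v <- res$x + lb
  # guard against silent solver failure
  if (max(abs(S %*% v)) > 1e-6 || any(v < lb - 1e-6) || any(v > ub + 1e-6)) {
    return(list(status = "error", objval = NA_real_, v = rep(NA_real_, n)))
  }
  list(status = "optimal", objval = sum(cvec * v), v = unname(v))
}

# At a fixed objective value z, minimise sum(|v|) via v = p - n, p, n >= 0.
# Returns the parsimonious optimal vector (or NULL on failure).
solve_parsimony_lp <- function(S, lb, ub, cvec, zstar) {
  S <- as_dense(S)
  n <- ncol(S)
  Aeq <- rbind(cbind(S, -S), c(cvec, -cvec))
  beq <- c(rep(0, nrow(S)), zstar)
  # p - n within [lb, ub]:  (p - n) <= ub  and  -(p - n) <= -lb
  A <- rbind(cbind(diag(n), -diag(n)), cbind(-diag(n), diag(n)))
  b <- c(ub, -lb)
  res <- tryCatch(
    with_seed(1L, pracma::linprog(cc = rep(1, 2 * n), A = A, b = b, Aeq = Aeq, beq = beq,
                                  maximize = FALSE, maxiter = 200 + 40 * n)),
    error = function(e) NULL)
  if (is.null(res) || is.null(res$errno) || res$errno != 1 || anyNA(res$x)) return(NULL)
  v <- res$x[seq_len(n)] - res$x[n + seq_len(n)]
  if (max(abs(S %*% v)) > 1e-6 || any(v < lb - 1e-6) || any(v > ub + 1e-6) ||
      abs(sum(cvec * v) - zstar) > 1e-6) {
    return(NULL)
  }
  unname(v)
}

# Objective coefficient vector selecting one reaction.
objective_cvec <- function(model, objective_id) {
  if (!objective_id %in% model$reactions) {
    stop_scflux(sprintf("unknown objective reaction '%s'", objective_id),
                class = "scflux_validation_error")
  }
  as.numeric(model$reactions == objective_id)
}
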