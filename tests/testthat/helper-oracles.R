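# Independent oracles used across the suite. These deliberately do not share
# code paths with the package: the LP oracle is boot::simplex with its own
# standard-form reduction, and the GPR oracle evaluates a shunting-yard
# postfix queue instead of a parse tree.

# ---- LP oracle --------------------------------------------------------------
# max/min cvec'v  s.t.  S v = 0, lb <= v <= ub, via boot::simplex on the
# shifted variable x = v - lb >= 0 with flipped rows for nonnegative RHS.
oracle_lp <- function(S, lb, ub, cvec, maximize = TRUE) {
  S <- as.matrix(S)
  # presolve in the shifted space x = v - lb >= 0: a zero-RHS equality row
  # whose free coefficients all share one sign forces those variables to
  # their lower bound; iterate to a fixpoint (handles degenerate knockouts
  # that a textbook simplex cannot pivot through)
  repeat {
    free <- (ub - lb) > 0
    b <- as.numeric(-S %*% lb)
    changed <- FALSE
    for (i in seq_len(nrow(S))) {
      coef <- S[i, ][free]          # named even when one column survives
      if (!any(coef != 0)) {
        if (abs(b[i]) > 1e-9) return(list(status = "infeasible", objval = NA_real_))
        next
      }
      if (b[i] == 0 && (all(coef >= 0) || all(coef <= 0))) {
        hit <- names(coef)[coef != 0]
        if (length(hit)) {
          ub[hit] <- lb[hit]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  free <- (ub - lb) > 0
  if (!any(free)) {
    v <- lb
    if (max(abs(S %*% v)) > 1e-9) return(list(status = "infeasible", objval = NA_real_))
    return(list(status = "optimal", objval = sum(cvec * v), v = v))
  }
  b3 <- as.numeric(-S %*% lb)
  A3 <- S[, free, drop = FALSE]
  neg <- b3 < 0
  A3[neg, ] <- -A3[neg, ]
  b3[neg] <- -b3[neg]
  zero_row <- apply(A3 == 0, 1, all)
  if (any(zero_row & abs(b3) > 1e-9)) return(list(status = "infeasible", objval = NA_real_))
  A3 <- A3[!zero_row, , drop = FALSE]; b3 <- b3[!zero_row]
  res <- boot::simplex(a = cvec[free], A1 = diag(sum(free)), b1 = (ub - lb)[free],
                       A3 = A3, b3 = b3, maxi = maximize,
                       n.iter = 50 * (nrow(S) + ncol(S)))
  if (res$solved != 1) return(list(status = "infeasible", objval = NA_real_))
  v <- lb
  v[free] <- as.numeric(res$soln) + lb[free]
  list(status = "optimal", objval = sum(cvec * v), v = v)
}

oracle_fva <- function(model) {
  t(vapply(seq_along(model$reactions), function(j) {
    cvec <- as.numeric(seq_along(model$reactions) == j)
    c(min = oracle_lp(model$S, model$lower_bounds, model$upper_bounds, cvec, FALSE)$objval,
      max = oracle_lp(model$S, model$lower_bounds, model$upper_bounds, cvec, TRUE)$objval)
  }, c(min = 0, max = 0)))
}

oracle_essential <- function(model, objective_id) {
  cvec <- as.numeric(model$reactions == objective_id)
  ess <- vapply(seq_along(model$reactions), function(j) {
    lb <- model$lower_bounds; ub <- model$upper_bounds
    lb[j] <- 0; ub[j] <- 0
    r <- oracle_lp(model$S, lb, ub, cvec, TRUE)
    r$status != "optimal" || r$objval <= 1e-9
  }, logical(1))
  model$reactions[ess]
}

# ---- GPR oracle -------------------------------------------------------------
# Shunting-yard to postfix, then stack evaluation with the RAS semantics
# (AND = min of non-missing, OR = sum of non-missing, all-missing = NA).
oracle_eval_gpr <- function(s, expr) {
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  out <- character(); ops <- character()
  prec <- c(or = 1, and = 2)
  for (tk in toks) {
    lt <- tolower(tk)
    if (lt %in% c("and", "or")) {
      while (length(ops) && ops[length(ops)] %in% c("and", "or") &&
             prec[[ops[length(ops)]]] >= prec[[lt]]) {
        out <- c(out, ops[length(ops)]); ops <- ops[-length(ops)]
      }
      ops <- c(ops, lt)
    } else if (tk == "(") {
      ops <- c(ops, tk)
    } else if (tk == ")") {
      while (length(ops) && ops[length(ops)] != "(") {
        out <- c(out, ops[length(ops)]); ops <- ops[-length(ops)]
      }
      ops <- ops[-length(ops)]
    } else {
      out <- c(out, tk)
    }
  }
  out <- c(out, rev(ops))
  stack <- list()
  comb <- function(a, b, f) {
    if (is.na(a) && is.na(b)) NA_real_
    else if (is.na(a)) b
    else if (is.na(b)) a
    else f(a, b)
  }
  for (tk in out) {
    lt <- tolower(tk)
    if (lt %in% c("and", "or")) {
      b <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- if (lt == "and") comb(a, b, min) else comb(a, b, `+`)
      stack[[length(stack) + 1]] <- v
    } else {
      v <- if (tk %in% names(expr)) as.numeric(expr[[tk]]) else NA_real_
      stack[[length(stack) + 1]] <- v
    }
  }
  stack[[1]]
}

# Random GPR rule over a gene pool: returns the rule string.
random_gpr <- function(n_genes, pool, depth = 0) {
  if (n_genes == 1 || depth > 3) {
    return(sample(pool, 1))
  }
  split <- sample(seq_len(n_genes - 1), 1)
  op <- sample(c("and", "or", "AND", "Or"), 1)
  lhs <- random_gpr(split, pool, depth + 1)
  rhs <- random_gpr(n_genes - split, pool, depth + 1)
  if (stats::runif(1) < 0.4) lhs <- paste0("(", lhs, ")")
  if (stats::runif(1) < 0.4) rhs <- paste0("(", rhs, ")")
  paste(lhs, op, rhs)
}

# ---- small fixtures ---------------------------------------------------------
tiny_expr <- function(values, layer = "normalized") {
  expr_matrix(values, layer = layer)
}

rich_branched <- function() apply_rich_medium(make_toy_model("branched"), 1000)
rich_chain3 <- function(uptake = 10) apply_rich_medium(make_toy_model("chain3"), uptake)
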