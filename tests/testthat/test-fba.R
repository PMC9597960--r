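test_that("essential sets match brute-force knockout enumeration on both presets", {
  for (build in list(rich_chain3, rich_branched)) {
    m <- build()
    ess <- find_essential(m)
    expect_setequal(ess$reactions, oracle_essential(m, m$objective))
    expect_true(m$objective %in% ess$reactions)   # the target is always essential
  }
  # chain: every reaction is essential
  expect_setequal(find_essential(rich_chain3())$reactions, c("EX_a", "CONV", "GROWTH"))
  # branched: the parallel branch reactions are not essential
  ess_b <- find_essential(rich_branched())$reactions
  expect_false(any(c("P_upper", "R_B1", "R_B2") %in% ess_b))
  expect_setequal(ess_b, c("EX_glc", "EX_o2", "T_glc", "T_o2", "R_resp", "BIOMASS"))
})

test_that("essentiality is undefined on a dead model", {
  m <- make_toy_model("chain3")    # uptake closed: baseline optimum 0
  expect_error(find_essential(m), class = "scflux_infeasible_error")
})

full_bounds <- function(model, fva) {
  # bounds object in which every cell sits at the unconstrained envelope
  genes <- model_genes(model)
  vals <- matrix(1, length(genes), 2, dimnames = list(genes, c("c1", "c2")))
  ras_bounds(model, fva, compute_ras(model, tiny_expr(vals)))
}

test_that("per-cell FBA attains the chain uptake cap and respects essential zeros", {
  m <- rich_chain3(uptake = 10)
  fva <- run_fva(m)
  b <- full_bounds(m, fva)
  sol <- solve_cell_fba(m, b, "c1")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 10)
  expect_equal(unname(sol$fluxes["CONV"]), 10)

  # zero upper bound on an essential reaction forces a zero optimum
  b0 <- b
  b0$U["CONV", "c1"] <- 0
  b0$L["CONV", "c1"] <- 0
  sol0 <- solve_cell_fba(m, b0, "c1")
  expect_equal(sol0$objective, 0)

  expect_error(solve_cell_fba(m, b, "ghost"), class = "scflux_validation_error")
})

test_that("the per-cell optimum equals an FVA-style oracle under the same bounds", {
  m <- rich_branched()
  fva <- run_fva(m)
  genes <- model_genes(m)
  set.seed(12)
  vals <- matrix(rpois(length(genes) * 3, 25) + 1, ncol = 3,
                 dimnames = list(genes, paste0("c", 1:3)))
  b <- ras_bounds(m, fva, compute_ras(m, tiny_expr(vals)))
  for (cell in colnames(b$L)) {
    sol <- solve_cell_fba(m, b, cell)
    want <- oracle_lp(m$S, b$L[, cell], b$U[, cell],
                      as.numeric(m$reactions == m$objective))
    expect_equal(sol$objective, want$objval, tolerance = 1e-6)
    # the parsimonious vertex still attains the optimum and is feasible
    expect_lt(max(abs(as.matrix(m$S) %*% sol$fluxes)), 1e-6)
    expect_true(all(sol$fluxes >= b$L[, cell] - 1e-6))
    expect_true(all(sol$fluxes <= b$U[, cell] + 1e-6))
  }
})

test_that("the optimum is invariant to reaction reordering", {
  m <- rich_branched()
  fva <- run_fva(m)
  b <- full_bounds(m, fva)
  sol <- solve_cell_fba(m, b, "c1")

  perm <- c(3, 1, 4, 2, 7, 9, 5, 8, 6)
  m2 <- metabolic_model(m$S[, perm], m$lower_bounds[perm], m$upper_bounds[perm],
                        gpr = m$gpr[perm], exchange = m$exchange[perm],
                        objective = m$objective)
  fva2 <- run_fva(m2)
  b2 <- full_bounds(m2, fva2)
  sol2 <- solve_cell_fba(m2, b2, "c1")
  expect_equal(sol2$objective, sol$objective, tolerance = 1e-9)
  expect_equal(sol2$fluxes[m$reactions], sol$fluxes, tolerance = 1e-6)
})

test_that("with all-max RAS, every cell reaches the unconstrained optimum", {
  m <- rich_branched()
  fva <- run_fva(m)
  b <- full_bounds(m, fva)
  fm <- build_flux_matrix(m, b)
  base <- oracle_lp(m$S, m$lower_bounds, m$upper_bounds,
                    as.numeric(m$reactions == m$objective))$objval
  expect_equal(unname(fm$objective_values), rep(base, 2), tolerance = 1e-6)
  expect_true(all(fm$status == "optimal"))
  # steady-state residual of every reported column
  expect_lt(max(abs(as.matrix(m$S) %*% fm$values)), 1e-6)
})

test_that("flux_qc removes exactly the cells with a zero essential RAS", {
  m <- rich_branched()
  fva <- run_fva(m)
  genes <- model_genes(m)
  vals <- matrix(10, length(genes), 3, dimnames = list(genes, c("keep", "dead1", "dead2")))
  vals["G1", "dead1"] <- 0            # T_glc (essential) zero
  vals["G4", "dead2"] <- 0            # R_B1 (non-essential) zero: survives
  ras <- compute_ras(m, tiny_expr(vals))
  ess <- find_essential(m)
  fm <- build_flux_matrix(m, ras_bounds(m, fva, ras))

  qc <- flux_qc(fm, ras, ess)
  expect_setequal(colnames(qc$values), c("keep", "dead2"))
  log <- attr(qc, "removal_log")
  expect_equal(log$removed, c(FALSE, TRUE, FALSE))
  expect_equal(log$n_zero_essential[2], 1L)

  # plain bounds + zero essential RAS force a zero objective before QC
  expect_equal(unname(fm$objective_values["dead1"]), 0, tolerance = 1e-9)

  vals_all <- vals; vals_all["G1", ] <- 0
  ras_all <- compute_ras(m, tiny_expr(vals_all))
  fm_all <- build_flux_matrix(m, ras_bounds(m, fva, ras_all))
  expect_error(flux_qc(fm_all, ras_all, ess), class = "scflux_empty_error")
})

test_that("heavy dropout without denoising removes most cells; denoising rescues them", {
  fx <- end_to_end_fixture("branched", n_cells = 50, seed = 6)
  m <- apply_rich_medium(fx$model)
  fva <- run_fva(m)
  ess <- find_essential(m)
  x <- normalize_total(qc_filter(fx$counts, 10, 3))

  ras_raw <- compute_ras(m, x)
  fm_raw <- build_flux_matrix(m, ras_bounds(m, fva, ras_raw))
  qc_raw <- flux_qc(fm_raw, ras_raw, ess)
  removed_raw <- mean(attr(qc_raw, "removal_log")$removed)

  ras_den <- compute_ras(m, diffusion_denoise(x, seed = 6))
  fm_den <- build_flux_matrix(m, ras_bounds(m, fva, ras_den))
  qc_den <- flux_qc(fm_den, ras_den, ess)
  removed_den <- mean(attr(qc_den, "removal_log")$removed)

  expect_gt(removed_raw, 0.5)
  expect_lt(removed_den, 0.1)
})
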