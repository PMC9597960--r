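test_that("FVA on a linear chain forces equal envelopes along the chain", {
  m <- rich_chain3(uptake = 10)       # uptake in [-10, 0]
  fva <- run_fva(m)
  expect_equal(fva$max[fva$reaction == "CONV"], 10)
  expect_equal(fva$max[fva$reaction == "GROWTH"], 10)
  expect_equal(fva$min[fva$reaction == "CONV"], 0)
  expect_equal(fva$min[fva$reaction == "EX_a"], -10)
  expect_equal(fva$max[fva$reaction == "EX_a"], 0)
})

test_that("a reaction fixed at zero has a degenerate envelope", {
  m <- rich_chain3()
  m$lower_bounds["CONV"] <- 0
  m$upper_bounds["CONV"] <- 0
  fva <- run_fva(m)
  expect_equal(fva$min[fva$reaction == "CONV"], 0)
  expect_equal(fva$max[fva$reaction == "CONV"], 0)
  expect_equal(fva$max[fva$reaction == "GROWTH"], 0)   # chain: everything dies
})

test_that("FVA envelopes on both presets match the independent LP oracle", {
  for (build in list(rich_chain3, rich_branched)) {
    m <- build()
    fva <- run_fva(m)
    want <- oracle_fva(m)
    expect_equal(fva$min, unname(want[, "min"]), tolerance = 1e-6)
    expect_equal(fva$max, unname(want[, "max"]), tolerance = 1e-6)
    expect_true(all(fva$min <= fva$max + 1e-9))
    expect_true(all(fva$min >= m$lower_bounds - 1e-9))
    expect_true(all(fva$max <= m$upper_bounds + 1e-9))
  }
})

test_that("infeasible base problems are diagnosed", {
  m <- rich_chain3()
  # force a contradiction: the chain must carry >= 5 flux but uptake is closed
  m$lower_bounds["EX_a"] <- 0
  m$lower_bounds["GROWTH"] <- 5
  expect_error(run_fva(m), class = "scflux_infeasible_error")
})

make_ras_fixture <- function(model, vals) {
  genes <- model_genes(model)
  x <- tiny_expr(vals)
  compute_ras(model, x)
}

test_that("plain RAS bounds rescale envelopes and zero out dead reactions", {
  m <- rich_branched()
  fva <- run_fva(m)
  genes <- model_genes(m)
  # cell2 attains the max RAS everywhere (double cell1); R_B1 is zero in all cells
  vals <- matrix(c(rep(10, length(genes)), rep(20, length(genes))), ncol = 2,
                 dimnames = list(genes, c("c1", "c2")))
  vals[c("G4", "G5"), ] <- 0
  ras <- make_ras_fixture(m, vals)
  b <- ras_bounds(m, fva, ras)

  Fl <- setNames(fva$min, fva$reaction); Fu <- setNames(fva$max, fva$reaction)
  # max-attaining cell recovers the envelope exactly
  expect_equal(b$U["T_glc", "c2"], unname(Fu["T_glc"]))
  expect_equal(b$L["T_glc", "c2"], unname(Fl["T_glc"]))
  # half-max cell gets half the envelope
  expect_equal(b$U["T_glc", "c1"], unname(Fu["T_glc"]) / 2)
  # all-zero RAS row pins the reaction to zero for every cell
  expect_equal(unname(b$U["R_B1", ]), c(0, 0))
  expect_equal(unname(b$L["R_B1", ]), c(0, 0))
  # GPR-less internal reactions keep their envelope; exchanges keep the medium
  expect_equal(unname(b$U["BIOMASS", ]), rep(unname(Fu["BIOMASS"]), 2))
  expect_equal(unname(b$L["EX_glc", ]), rep(-1000, 2))
  expect_true(all(b$L <= b$U))

  ras_neg <- ras
  ras_neg$values[1, 1] <- -1
  expect_error(ras_bounds(m, fva, ras_neg), class = "scflux_validation_error")
})

test_that("epsilon bounds telescope at the extremes and recover plain bounds as eps -> 0", {
  m <- rich_branched()
  fva <- run_fva(m)
  genes <- model_genes(m)
  set.seed(9)
  vals <- matrix(rpois(length(genes) * 4, 15), ncol = 4,
                 dimnames = list(genes, paste0("c", 1:4)))
  vals["G1", 1] <- 0            # a zero-RAS cell for T_glc
  ras <- make_ras_fixture(m, vals)

  eps <- 0.01
  be <- epsilon_bounds(m, fva, ras, eps)
  # ratio 0 gives the residual capacity band (-eps, +eps)
  expect_equal(be$U["T_glc", "c1"], eps)
  expect_equal(be$L["T_glc", "c1"], -eps)
  # the max-RAS cell telescopes back to the envelope
  jmax <- which.max(ras$values["T_glc", ])
  Fu <- fva$max[fva$reaction == "T_glc"]; Fl <- fva$min[fva$reaction == "T_glc"]
  expect_equal(unname(be$U["T_glc", jmax]), Fu)
  expect_equal(unname(be$L["T_glc", jmax]), Fl)

  # elementwise limit eps -> 0 equals the plain strategy
  bp <- ras_bounds(m, fva, ras)
  b0 <- epsilon_bounds(m, fva, ras, 1e-13)
  expect_equal(b0$U, bp$U, tolerance = 1e-12)
  expect_equal(b0$L, bp$L, tolerance = 1e-12)

  expect_error(epsilon_bounds(m, fva, ras, 0))
})

test_that("bounds are invariant to rescaling a reaction's RAS row", {
  m <- rich_branched()
  fva <- run_fva(m)
  genes <- model_genes(m)
  set.seed(10)
  vals <- matrix(rpois(length(genes) * 3, 20) + 1, ncol = 3,
                 dimnames = list(genes, paste0("c", 1:3)))
  ras <- make_ras_fixture(m, vals)
  ras2 <- ras
  ras2$values["T_glc", ] <- ras2$values["T_glc", ] * 37.5
  expect_equal(ras_bounds(m, fva, ras2)$U, ras_bounds(m, fva, ras)$U)
  expect_equal(epsilon_bounds(m, fva, ras2)$L, epsilon_bounds(m, fva, ras)$L)
})

test_that("within a reaction, plain bounds are monotone in RAS", {
  m <- rich_branched()
  fva <- run_fva(m)
  genes <- model_genes(m)
  vals <- matrix(rep(c(1, 5, 2, 9), each = length(genes)), ncol = 4,
                 dimnames = list(genes, paste0("c", 1:4)))
  ras <- make_ras_fixture(m, vals)
  b <- ras_bounds(m, fva, ras)
  ord <- order(ras$values["T_glc", ])
  expect_true(all(diff(b$U["T_glc", ord]) >= 0))
})
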