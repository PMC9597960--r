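test_that("parsing respects precedence, parentheses, and classification", {
  r <- parse_gpr("A")
  expect_equal(r$class, "single")
  expect_equal(r$genes, "A")

  r <- parse_gpr("A or B and C")
  expect_equal(r$class, "complex")
  expect_equal(r$tree$op, "or")            # AND binds tighter than OR
  expect_equal(r$tree$children[[2]]$op, "and")

  r <- parse_gpr("(A or B) and C")
  expect_equal(r$tree$op, "and")
  expect_equal(r$tree$children[[1]]$op, "or")

  expect_equal(parse_gpr("A or B or C")$class, "or_only")
  expect_equal(parse_gpr("A and B")$class, "and_only")
  expect_equal(parse_gpr("(A)")$class, "single")
})

test_that("parse errors carry a position and a clear class", {
  expect_error(parse_gpr("(A or B"), class = "scflux_parse_error")
  expect_error(parse_gpr("A and"), class = "scflux_parse_error")
  expect_error(parse_gpr("and A"), class = "scflux_parse_error")
  expect_error(parse_gpr(""), class = "scflux_parse_error")
  err <- tryCatch(parse_gpr("(A or B"), error = identity)
  expect_match(conditionMessage(err), "position 1")
})

test_that("evaluation implements min-over-AND, sum-over-OR, and the missing-gene rules", {
  expect_equal(eval_gpr(parse_gpr("A and B"), list(A = 2, B = 5)), 2)
  expect_equal(eval_gpr(parse_gpr("A or B"), list(A = 2, B = 5)), 7)
  # a missing gene drops out of the rule instead of poisoning it
  expect_equal(eval_gpr(parse_gpr("A and B"), list(A = 3)), 3)
  expect_equal(eval_gpr(parse_gpr("A or B"), list(A = 3)), 3)
  expect_true(is.na(eval_gpr(parse_gpr("A or B"), list())))
  # zero is a measured number, not a missing value
  expect_equal(eval_gpr(parse_gpr("A and B"), list(A = 0, B = 5)), 0)
  # vectorised over cells
  expect_equal(eval_gpr(parse_gpr("A and B"), list(A = c(1, 4), B = c(2, 3))), c(1, 3))
})

test_that("evaluation is monotone in every gene's value", {
  set.seed(11)
  pool <- LETTERS[1:4]
  for (i in 1:50) {
    s <- random_gpr(sample(2:4, 1), pool)
    rule <- parse_gpr(s)
    vals <- as.list(setNames(runif(4, 0, 10), pool))
    base <- eval_gpr(rule, vals)
    g <- sample(pool, 1)
    vals2 <- vals
    vals2[[g]] <- vals[[g]] + runif(1, 0, 5)
    expect_gte(eval_gpr(rule, vals2), base)
  }
})

test_that("RAS matrix matches hand evaluation, drops uncovered reactions, reports coverage", {
  m <- make_toy_model("branched")
  genes <- c("G1", "G2", "G3", "G4", "G5", "G6", "G9", "G10", "G11")  # G7, G8 absent
  vals <- matrix(seq_len(length(genes) * 2), nrow = length(genes),
                 dimnames = list(genes, c("c1", "c2")))
  x <- tiny_expr(vals)
  ras <- compute_ras(m, x)

  v <- function(g, cell) vals[g, cell]
  for (cell in c("c1", "c2")) {
    expect_equal(ras$values["T_glc", cell], v("G1", cell))
    expect_equal(ras$values["P_upper", cell], v("G2", cell) + v("G3", cell))
    expect_equal(ras$values["R_B1", cell], min(v("G4", cell), v("G5", cell)))
    # complex rule with G7, G8 missing: OR(G6, AND(G7,G8)) collapses to G6
    expect_equal(ras$values["R_B2", cell], v("G6", cell))
    expect_equal(ras$values["R_resp", cell], min(v("G10", cell), v("G11", cell)))
  }
  expect_equal(ras$coverage, 9 / 11)
  expect_length(ras$dropped, 0)

  # a reaction whose genes are all absent is dropped and reported
  x2 <- tiny_expr(vals[setdiff(genes, c("G4", "G5")), , drop = FALSE])
  ras2 <- compute_ras(m, x2)
  expect_false("R_B1" %in% rownames(ras2$values))
  expect_equal(ras2$dropped, "R_B1")
})

test_that("compute_ras commutes with cell permutation", {
  m <- make_toy_model("branched")
  set.seed(3)
  vals <- matrix(rpois(11 * 6, 20), nrow = 11,
                 dimnames = list(model_genes(m), paste0("c", 1:6)))
  x <- tiny_expr(vals)
  perm <- c(4, 2, 6, 1, 5, 3)
  xp <- tiny_expr(vals[, perm])
  expect_equal(compute_ras(m, xp)$values, compute_ras(m, x)$values[, perm])
})

test_that("sparsity reports count zeros overall, per cell, and on restricted rows", {
  m <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  rep0 <- sparsity_report(m)
  expect_equal(rep0$overall, 0.5)
  expect_equal(rep0$per_cell$zero_fraction, c(0.5, 0.5))
  expect_equal(sparsity_report(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))))$overall, 1)

  rep1 <- sparsity_report(m, essential_set = "r1")
  expect_equal(rep1$essential_overall, 0.5)
  expect_equal(rep1$per_cell$essential_zero_fraction, c(0, 1))
  expect_error(sparsity_report(m, essential_set = "nope"),
               class = "scflux_validation_error")
})

test_that("gpr evaluation agrees with an independent postfix oracle on random rules", {
  set.seed(2024)
  pool <- c("g1", "g2", "g3", "g4", "g5", "g6")
  n_checked <- 0L
  for (i in seq_len(1000)) {
    s <- random_gpr(sample(2:6, 1), pool)
    expr <- as.list(setNames(round(runif(length(pool), 0, 50), 2), pool))
    # randomly knock genes out of the map entirely (missing expression)
    drop <- runif(length(pool)) < 0.3
    expr[drop] <- NULL
    got <- eval_gpr(parse_gpr(s), expr)
    want <- oracle_eval_gpr(s, expr)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(want)) expect_equal(got, want)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 1000L)
})
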