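test_that("two near-identical cells converge to their pair mean under long diffusion", {
  vals <- matrix(c(4, 6, 2,
                   4, 6, 0), nrow = 3,
                 dimnames = list(c("g1", "g2", "g3"), c("c1", "c2")))
  out <- diffusion_denoise(tiny_expr(vals), n_pcs = 1, knn = 1, decay = 1, t = 50)
  target <- rowMeans(vals)
  # the 2x2 kernel is symmetric, hence doubly stochastic: P^t -> uniform
  expect_equal(unname(as.matrix(out$values)[, 1]), unname(target), tolerance = 1e-6)
  expect_equal(unname(as.matrix(out$values)[, 2]), unname(target), tolerance = 1e-6)
  expect_equal(out$layer, "denoised")
})

test_that("t = 0 is the identity and inputs are validated", {
  vals <- matrix(runif(12), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  x <- tiny_expr(vals)
  out <- diffusion_denoise(x, knn = 2, t = 0)
  expect_equal(as.matrix(out$values), vals)
  expect_equal(out$layer, "denoised")

  expect_error(diffusion_denoise(x, knn = 4), class = "scflux_validation_error")
  neg <- vals; neg[1] <- -1
  expect_error(diffusion_denoise(tiny_expr(neg, layer = "denoised"), knn = 2),
               class = "scflux_validation_error")
})

test_that("a constant matrix is returned unchanged with a degenerate-PCA warning", {
  vals <- matrix(3, 4, 5, dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  expect_warning(out <- diffusion_denoise(tiny_expr(vals), knn = 2, t = 2),
                 class = "scflux_degenerate_warning")
  expect_equal(as.matrix(out$values), vals)
})

test_that("diffusion keeps profiles in the convex hull and strictly reduces zeros", {
  set.seed(8)
  fx <- end_to_end_fixture("branched", n_cells = 50, seed = 8)
  x <- normalize_total(qc_filter(fx$counts, 5, 1))
  out <- diffusion_denoise(x, seed = 8)
  m_in <- as.matrix(x$values); m_out <- as.matrix(out$values)
  expect_true(all(m_out >= 0))
  expect_equal(dim(m_out), dim(m_in))
  expect_identical(colnames(m_out), colnames(m_in))
  # convex combinations cannot exceed the per-gene input range
  expect_true(all(m_out <= apply(m_in, 1, max) + 1e-8))
  expect_true(all(m_out >= apply(m_in, 1, min) - 1e-8))
  # dropout zeros vanish unless an entire neighbourhood is zero
  expect_lt(mean(m_out == 0), mean(m_in == 0))
})

test_that("denoising restores a planted correlation damaged by dropout", {
  fx <- end_to_end_fixture("branched", n_cells = 100, seed = 21)
  x <- normalize_total(qc_filter(fx$counts, 10, 3))
  out <- diffusion_denoise(x, seed = 21)
  rho_truth <- cor(as.matrix(fx$truth$values)["CORA", ], as.matrix(fx$truth$values)["CORB", ],
                   method = "spearman")
  rho_obs <- cor(as.matrix(x$values)["CORA", ], as.matrix(x$values)["CORB", ],
                 method = "spearman")
  rho_den <- cor(as.matrix(out$values)["CORA", ], as.matrix(out$values)["CORB", ],
                 method = "spearman")
  expect_gt(rho_den, rho_obs)
  expect_lt(abs(rho_den - rho_truth), abs(rho_obs - rho_truth))
})

test_that("denoising stages wire into the RAS computation correctly", {
  fx <- end_to_end_fixture("branched", n_cells = 60, seed = 4)
  x <- normalize_total(qc_filter(fx$counts, 10, 3))
  m <- fx$model

  r_none <- apply_denoising(m, x, "none")
  expect_identical(r_none$values, compute_ras(m, x)$values)
  expect_identical(attr(r_none, "denoise_stage"), "none")

  r_counts <- apply_denoising(m, x, "on_counts", seed = 4)
  r_ras <- apply_denoising(m, x, "on_ras", seed = 4)
  expect_identical(dim(r_counts$values), dim(r_none$values))
  expect_identical(dim(r_ras$values), dim(r_none$values))
  expect_identical(attr(r_ras, "denoise_stage"), "on_ras")
  # both stages reduce zero RAS values on the dropout fixture
  expect_lt(mean(r_counts$values == 0), mean(r_none$values == 0))
  expect_lt(mean(r_ras$values == 0), mean(r_none$values == 0))
})

test_that("external denoiser adapters error usefully and round-trip shapes", {
  m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  expect_error(
    external_denoiser_adapter(m, "enhance", available_fn = function(tool) FALSE),
    regexp = "install",
    class = "scflux_tool_error")

  # stub runner standing in for a real tool: shape-preserving round trip
  ok <- external_denoiser_adapter(
    m, "magic", workdir = tempfile(),
    available_fn = function(tool) TRUE,
    run_fn = function(fin, fout, tool) {
      v <- as.matrix(read.csv(fin, row.names = 1, check.names = FALSE))
      write.csv(v + 1, fout, row.names = TRUE)
    })
  expect_equal(dim(ok), dim(m))
  expect_equal(unname(ok), unname(m + 1))

  # a tool that changes the shape is rejected
  expect_error(
    external_denoiser_adapter(
      m, "magic", workdir = tempfile(),
      available_fn = function(tool) TRUE,
      run_fn = function(fin, fout, tool) {
        write.csv(matrix(1, 1, 1), fout, row.names = TRUE)
      }),
    class = "scflux_tool_error")
})
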