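#' Graph-diffusion denoising of a counts or RAS matrix
#'
#' Removes putative false zeros (dropout) by smoothing each cell's profile
#' over its nearest neighbours: (1) a cell-cell kNN graph is built on the top
#' principal components of the input; (2) an adaptive Gaussian kernel
#' \eqn{K_{ij} = \exp(-(d_{ij}/\sigma_i)^{decay})} with \eqn{\sigma_i} the
#' distance to the `knn`-th neighbour gives affinities, symmetrised as
#' \eqn{(K + K^\top)/2}; (3) rows are normalised to a Markov matrix `P`;
#' (4) the output is \eqn{P^t} times the cell profiles. Each denoised profile
#' is therefore a convex combination of input profiles: nonnegativity is
#' conserved, cells keep their number and order, and a zero can only survive
#' if an entire neighbourhood is zero. `t = 0` is admitted as the identity.
#'
#' The same operation applies unchanged to a RAS matrix, where reactions play
#' the role of genes.
#'
#' @param x an `expr_matrix`, `ras_matrix`, or plain features x cells matrix.
#' @param n_pcs number of principal components for the distance space
#'   (default 20, capped at the data dimensions).
#' @param knn neighbourhood size (default 15); needs at least `knn + 1` cells.
#' @param decay kernel sharpness exponent (default 2: a sharply local
#'   adaptive kernel).
#' @param t diffusion time, a nonnegative integer (default 3).
#' @param seed RNG seed recorded for provenance (the computation itself is
#'   deterministic).
#' @return The same type as `x`, layer tagged `denoised`.
#' @export
diffusion_denoise <- function(x, n_pcs = 20, knn = 15, decay = 2, t = 3, seed = 0) {
  vals <- if (inherits(x, c("expr_matrix", "ras_matrix"))) as_dense(x$values) else as_dense(x)
  if (any(vals < 0)) {
    stop_scflux("diffusion denoising expects nonnegative input",
                class = "scflux_validation_error")
  }
  n_cells <- ncol(vals)
  if (n_cells < knn + 1) {
    stop_scflux(sprintf("need at least knn + 1 = %d cells, have %d", knn + 1, n_cells),
                class = "scflux_validation_error")
  }
  stopifnot(t >= 0, t == round(t), decay > 0)
  M <- t(vals)                                 # cells x features
  if (t == 0) return(relabel_denoised(x, vals))
  if (all(apply(M, 2, stats::sd) == 0)) {
    warn_scflux("constant input matrix: degenerate PCA, returned unchanged",
                class = "scflux_degenerate_warning")
    return(relabel_denoised(x, vals))
  }
  k <- min(n_pcs, n_cells - 1, ncol(M))
  # the diffusion geometry is computed on square-root transformed values
  # (variance stabilisation: every gene contributes on a comparable scale,
  # and dropout noise does not grow with the mean); the diffusion operator
  # is then applied to the input on its original scale
  scores <- stats::prcomp(sqrt(M), center = TRUE, scale. = FALSE, rank. = k)$x
  D <- as.matrix(stats::dist(scores))
  # adaptive bandwidth: distance to the knn-th nearest (non-self) neighbour
  sigma <- apply(D, 1, function(d) sort(d[-which.min(d)])[knn])
  sigma <- pmax(sigma, 1e-12)
  K <- exp(-(D / sigma)^decay)
  # kernel support extends to 3*knn neighbours (bandwidth stays the knn-th
  # distance): wide enough to keep the graph connected within a population,
  # local enough that the decay suppresses far neighbours
  support <- min(3 * knn, n_cells - 1)
  for (i in seq_len(n_cells)) {
    ord <- order(D[i, ])
    drop <- setdiff(seq_len(n_cells), ord[seq_len(support + 1)])
    K[i, drop] <- 0
  }
  K <- (K + t(K)) / 2
  P <- K / rowSums(K)
  Pt <- P
  if (t > 1) for (s in seq_len(t - 1)) Pt <- Pt %*% P
  out <- t(Pt %*% M)
  dimnames(out) <- dimnames(vals)
  relabel_denoised(x, out)
}

relabel_denoised <- function(x, vals) {
  if (inherits(x, "expr_matrix")) {
    out <- expr_matrix(vals, layer = "denoised", obs = x$obs)
  } else if (inherits(x, "ras_matrix")) {
    out <- x
    out$values <- vals
    out$layer <- "denoised"
  } else {
    out <- vals
  }
  out
}

#' Wire denoising into the RAS computation
#'
#' The denoising comparison grid has three arms: denoise the counts before
#' computing RAS (`on_counts`), compute RAS first and denoise the RAS matrix
#' (`on_ras`), or no denoising (`none`). This helper runs the chosen arm and
#' records the stage.
#'
#' @param model a `metabolic_model`.
#' @param x a normalized `expr_matrix`.
#' @param stage one of `"on_counts"`, `"on_ras"`, `"none"`.
#' @param ... passed to [diffusion_denoise()].
#' @return A `ras_matrix` with attribute `denoise_stage`.
#' @export
apply_denoising <- function(model, x, stage = c("none", "on_counts", "on_ras"), ...) {
  stage <- match.arg(stage)
  ras <- switch(stage,
    none = compute_ras(model, x),
    on_counts = compute_ras(model, diffusion_denoise(x, ...)),
    on_ras = diffusion_denoise(compute_ras(model, x), ...)
  )
  attr(ras, "denoise_stage") <- stage
  ras
}

#' Adapter for external denoising tools
#'
#' Round-trips a matrix through an external denoiser (the original MAGIC,
#' ENHANCE, or SAVER implementations) with their default parameters. The tool
#' must be installed and importable; this package does not reimplement them
#' (the in-repo denoiser is [diffusion_denoise()]).
#'
#' @param m numeric features x cells matrix.
#' @param tool_name one of `"magic"`, `"enhance"`, `"saver"`.
#' @param workdir scratch directory for the file round-trip.
#' @param available_fn availability probe, exposed for testing; defaults to
#'   checking that the tool's python module (or R package, for SAVER)
#'   is importable.
#' @param run_fn runner, exposed for testing; takes (input csv, output csv,
#'   tool) and must write the denoised matrix.
#' @return The denoised matrix, same shape as `m`.
#' @export
external_denoiser_adapter <- function(m, tool_name = c("magic", "enhance", "saver"),
                                      workdir = tempdir(),
                                      available_fn = NULL, run_fn = NULL) {
  tool_name <- match.arg(tool_name)
  hints <- c(magic = "pip install magic-impute",
             enhance = "pip install enhance-sc (or clone the reference implementation)",
             saver = "install.packages('SAVER')")
  available_fn <- available_fn %||% default_tool_probe
  if (!isTRUE(available_fn(tool_name))) {
    stop_scflux(sprintf("denoiser '%s' is not available; install it with: %s",
                        tool_name, hints[[tool_name]]),
                class = "scflux_tool_error")
  }
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  fin <- file.path(workdir, "denoiser_input.csv")
  fout <- file.path(workdir, "denoiser_output.csv")
  utils::write.csv(as_dense(m), fin, row.names = TRUE)
  run_fn <- run_fn %||% default_tool_runner
  run_fn(fin, fout, tool_name)
  out <- as.matrix(utils::read.csv(fout, row.names = 1, check.names = FALSE))
  if (!identical(dim(out), dim(as_dense(m)))) {
    stop_scflux(sprintf("denoiser '%s' changed the matrix shape (%s -> %s)",
                        tool_name,
                        paste(dim(m), collapse = "x"), paste(dim(out), collapse = "x")),
                class = "scflux_tool_error")
  }
  dimnames(out) <- dimnames(as_dense(m))
  out
}

default_tool_probe <- function(tool) {
  if (tool == "saver") {
    return(requireNamespace("SAVER", quietly = TRUE))
  }
  module <- c(magic = "magic", enhance = "enhance")[[tool]]
  ok <- suppressWarnings(system2("python", c("-c", shQuote(sprintf("import %s", module))),
                                 stdout = FALSE, stderr = FALSE))
  identical(ok, 0L)
}

default_tool_runner <- function(fin, fout, tool) {
  script <- sprintf(
    "import pandas as pd; import %s as mod; m = pd.read_csv(%s, index_col=0);%s",
    tool, shQuote(fin),
    switch(tool,
      magic = sprintf(" out = mod.MAGIC().fit_transform(m.T).T; out.to_csv(%s)", shQuote(fout)),
      enhance = sprintf(" out = mod.enhance(m); out.to_csv(%s)", shQuote(fout)),
      saver = ""))
  if (tool == "saver") {
    den <- SAVER::saver(as.matrix(utils::read.csv(fin, row.names = 1, check.names = FALSE)))
    utils::write.csv(den$estimate, fout, row.names = TRUE)
    return(invisible(NULL))
  }
  status <- system2("python", c("-c", shQuote(script)))
  if (!identical(status, 0L)) {
    stop_scflux(sprintf("external denoiser '%s' failed (exit %s)", tool, status),
                class = "scflux_tool_error")
  }
  invisible(NULL)
}
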