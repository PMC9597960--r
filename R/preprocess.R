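#' Construct a single-cell expression matrix
#'
#' Light container for a genes x cells matrix plus per-cell annotations and
#' a layer tag recording what the values are (`raw` counts, `normalized`,
#' `lognormalized`, `denoised`).
#'
#' @param values numeric genes x cells matrix (base or `Matrix`), with gene
#'   identifiers as rownames and cell identifiers as colnames.
#' @param layer layer tag.
#' @param obs optional tibble of per-cell annotations with a `cell` column.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, layer = c("raw", "normalized", "lognormalized", "denoised"),
                        obs = NULL) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_scflux("expression values need gene rownames and cell colnames",
                class = "scflux_validation_error")
  }
  if (anyDuplicated(rownames(values))) {
    stop_scflux("duplicate gene identifiers; collapse them first (read_counts sums duplicates)",
                class = "scflux_validation_error")
  }
  if (layer %in% c("raw", "normalized") && any(as_dense(values) < 0)) {
    stop_scflux("negative values in a counts/normalized layer",
                class = "scflux_validation_error")
  }
  obs <- obs %||% tibble::tibble(cell = colnames(values))
  if (!all(colnames(values) %in% obs$cell)) {
    stop_scflux("obs does not cover all cells", class = "scflux_validation_error")
  }
  obs <- obs[match(colnames(values), obs$cell), , drop = FALSE]
  structure(list(values = values, layer = layer, obs = obs), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  extra <- setdiff(names(x$obs), "cell")
  if (length(extra)) cat("  per-cell annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a counts matrix
#'
#' Two formats: `mtx_dir` (a 10x-style directory with `matrix.mtx`,
#' `genes.tsv`, `barcodes.tsv`) or `csv` (dense, genes in rows, header row of
#' cell identifiers, first column of gene identifiers). Duplicate gene
#' identifiers are collapsed by summing their counts.
#'
#' @param path directory (for `mtx_dir`) or file path (for `csv`).
#' @param format `"mtx_dir"` or `"csv"`; guessed from `path` when missing.
#' @return A raw-layer `expr_matrix`.
#' @export
read_counts <- function(path, format = c("mtx_dir", "csv")) {
  if (length(format) > 1) format <- if (dir.exists(path)) "mtx_dir" else "csv"
  format <- match.arg(format, c("mtx_dir", "csv"))
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    genes_f <- file.path(path, "genes.tsv")
    cells_f <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes_f, cells_f)) {
      if (!file.exists(f)) stop_scflux(sprintf("missing file: %s", f), class = "scflux_io_error")
    }
    m <- as.matrix(Matrix::readMM(mtx))
    genes <- utils::read.table(genes_f, sep = "\t", stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.table(cells_f, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m)) {
      stop_scflux(sprintf(
        "dimension mismatch: matrix is %d x %d but %d genes / %d barcodes listed",
        nrow(m), ncol(m), length(genes), length(cells)), class = "scflux_io_error")
    }
    dimnames(m) <- list(genes, cells)
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  }
  m <- collapse_duplicate_genes(m)
  expr_matrix(m, layer = "raw")
}

collapse_duplicate_genes <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  g <- rownames(m)
  out <- rowsum(as_dense(m), group = g, reorder = FALSE)
  out[unique(g), , drop = FALSE]
}

#' Quality-filter cells and genes
#'
#' Removes, in this fixed order, (1) cells with fewer than
#' `min_genes_per_cell` detected (nonzero) genes, then (2) genes expressed in
#' fewer than `min_cells_per_gene` of the surviving cells. The order matters
#' and is pinned: cells first, then genes.
#'
#' @param x a raw-layer `expr_matrix`.
#' @param min_genes_per_cell integer threshold on detected genes per cell
#'   (default 2000, intended for whole-transcriptome data).
#' @param min_cells_per_gene integer threshold on cells per gene (default 3).
#' @return The filtered `expr_matrix`.
#' @export
qc_filter <- function(x, min_genes_per_cell = 2000, min_cells_per_gene = 3) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- as_dense(x$values)
  keep_cells <- colSums(m > 0) >= min_genes_per_cell
  if (!any(keep_cells)) {
    stop_scflux("qc_filter removed every cell; lower min_genes_per_cell",
                class = "scflux_empty_error")
  }
  m <- m[, keep_cells, drop = FALSE]
  keep_genes <- rowSums(m > 0) >= min_cells_per_gene
  m <- m[keep_genes, , drop = FALSE]
  expr_matrix(m, layer = x$layer, obs = x$obs[x$obs$cell %in% colnames(m), , drop = FALSE])
}

#' Normalise cells to a common total count
#'
#' Rescales every cell so that its column sum equals `target_sum`
#' (counts-per-million style total-count normalisation when
#' `target_sum = 1e6`). Within-cell expression ratios are preserved.
#'
#' @param x a raw-layer `expr_matrix` with positive per-cell totals.
#' @param target_sum the common total (default `1e6`).
#' @return A normalized-layer `expr_matrix`.
#' @export
normalize_total <- function(x, target_sum = 1e6) {
  stopifnot(inherits(x, "expr_matrix"), target_sum > 0)
  m <- as_dense(x$values)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop_scflux("cells with zero total counts; run qc_filter first",
                class = "scflux_validation_error")
  }
  m <- sweep(m, 2, target_sum / tot, `*`)
  expr_matrix(m, layer = "normalized", obs = x$obs)
}

#' Log-transform a normalized layer
#'
#' Applies `log(x + 1)` elementwise, tagging the layer `lognormalized`.
#'
#' @param x a normalized-layer `expr_matrix`.
#' @return A lognormalized `expr_matrix`.
#' @export
log_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- expr_matrix(log1p(as_dense(x$values)), layer = "normalized", obs = x$obs)
  out$layer <- "lognormalized"
  out
}

#' Score cell-cycle phase from S and G2M gene signatures
#'
#' Binned-control signature scoring: genes are ranked by mean expression
#' across cells and cut into `n_bins` bins; for every signature gene,
#' `ctrl_size` control genes are sampled (seeded) from the same bin; the
#' score of a cell is the mean expression of the signature genes minus the
#' mean expression of the pooled control genes. Both an S score and a G2M
#' score are computed on log-transformed values; the phase is `G1` when both
#' scores are negative and otherwise the phase of the larger score.
#'
#' @param x a normalized or lognormalized `expr_matrix` (a normalized layer
#'   is log1p-transformed internally).
#' @param s_genes,g2m_genes character vectors of signature gene identifiers.
#' @param n_bins number of expression bins (default 25).
#' @param ctrl_size control genes sampled per signature gene (default 50).
#' @param seed RNG seed for control sampling.
#' @return `x` with `s_score`, `g2m_score` and `phase` columns added to
#'   `$obs`.
#' @export
score_cell_cycle <- function(x, s_genes, g2m_genes, n_bins = 25, ctrl_size = 50, seed = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer == "raw") {
    stop_scflux("score_cell_cycle needs a normalized layer; run normalize_total first",
                class = "scflux_validation_error")
  }
  m <- as_dense(x$values)
  if (x$layer != "lognormalized") m <- log1p(m)
  for (nm in c("s_genes", "g2m_genes")) {
    sig <- get(nm)
    if (!length(intersect(sig, rownames(m)))) {
      stop_scflux(sprintf("no %s found in the matrix; missing: %s",
                          nm, paste(utils::head(sig, 10), collapse = ", ")),
                  class = "scflux_validation_error")
    }
  }
  gene_mean <- rowMeans(m)
  bins <- cut(rank(gene_mean, ties.method = "first"),
              breaks = max(1, min(n_bins, nrow(m))), labels = FALSE)
  score_one <- function(sig, seed_offset) {
    sig <- intersect(sig, rownames(m))
    ctrl <- with_seed(seed + seed_offset, {
      unlist(lapply(sig, function(g) {
        pool <- rownames(m)[bins == bins[match(g, rownames(m))]]
        sample(pool, min(ctrl_size, length(pool)))
      }))
    })
    colMeans(m[sig, , drop = FALSE]) - colMeans(m[unique(ctrl), , drop = FALSE])
  }
  s_score <- score_one(s_genes, 0L)
  g2m_score <- score_one(g2m_genes, 1L)
  # non-positive scores on both signatures mean no phase signal: G1
  phase <- ifelse(s_score <= 0 & g2m_score <= 0, "G1",
                  ifelse(s_score >= g2m_score, "S", "G2M"))
  x$obs$s_score <- unname(s_score)
  x$obs$g2m_score <- unname(g2m_score)
  x$obs$phase <- unname(phase)
  x
}
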