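#' Specify a synthetic single-cell experiment
#'
#' Defines the generative conditions for [simulate_counts()]: negative
#' binomial counts with population-specific mean programs, lognormal library
#' size variation, independent dropout (zero inflation), optional planted
#' gene-pair correlations, and optional cell-cycle programs.
#'
#' @param populations named list mapping population labels to per-gene mean
#'   vectors (all populations must share the same gene namespace).
#' @param n_cells integer cells per population (recycled across populations).
#' @param nb_dispersion negative binomial size parameter (default 2; smaller
#'   means more overdispersion).
#' @param dropout_rate probability that an observed entry is zeroed
#'   independently of its value (default 0.4) — the tractable model of false
#'   zeros. `mean_dependent_dropout = TRUE` switches to a logistic-in-log-mean
#'   alternative with the same average rate.
#' @param library_size_spread sdlog of the lognormal per-cell library size
#'   factor (default 0.2).
#' @param correlated_pairs optional tibble/data.frame with columns `gene_a`,
#'   `gene_b`, `rho`: pairs of genes co-regulated through a Gaussian copula
#'   on their negative binomial margins so that the pair's Spearman
#'   correlation equals `rho` (up to discreteness).
#' @param cellcycle_fraction named numeric proportions for phases
#'   `c(G1 = , S = , G2M = )`; genes named `SSIG*` / `G2MSIG*` in the
#'   namespace are upshifted by `cellcycle_strength` in cells of the
#'   matching phase.
#' @param cellcycle_strength fold-change of signature genes in their phase
#'   (default 4).
#' @param phase_programs optional named list (`S`, `G2M`) of named fold-change
#'   vectors applied to arbitrary genes in cells of that phase — used to
#'   plant a growth/cell-cycle coupling (cycling cells synthesise biomass
#'   faster).
#' @param mean_dependent_dropout logical, see `dropout_rate`.
#' @param seed RNG seed; identical specs give bit-identical outputs.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(populations,
                     n_cells = 100,
                     nb_dispersion = 2,
                     dropout_rate = 0.4,
                     library_size_spread = 0.2,
                     correlated_pairs = NULL,
                     cellcycle_fraction = NULL,
                     cellcycle_strength = 4,
                     phase_programs = NULL,
                     mean_dependent_dropout = FALSE,
                     seed = 0) {
  if (!is.list(populations) || is.null(names(populations)) ||
      anyDuplicated(names(populations))) {
    stop_scflux("populations must be a named list with unique labels",
                class = "scflux_config_error")
  }
  genes <- names(populations[[1]])
  for (p in populations) {
    if (is.null(names(p)) || !identical(sort(names(p)), sort(genes)) || any(p < 0)) {
      stop_scflux("every population needs the same gene namespace and nonnegative means",
                  class = "scflux_config_error")
    }
  }
  if (length(genes) < 2 || any(n_cells < 1)) {
    stop_scflux("degenerate spec: need >= 2 genes and >= 1 cell per population",
                class = "scflux_config_error")
  }
  stopifnot(dropout_rate >= 0, dropout_rate <= 1, nb_dispersion > 0,
            library_size_spread > 0)
  if (!is.null(cellcycle_fraction)) {
    stopifnot(all(c("G1", "S", "G2M") %in% names(cellcycle_fraction)),
              abs(sum(cellcycle_fraction) - 1) < 1e-8)
  }
  if (!is.null(phase_programs)) {
    stopifnot(all(names(phase_programs) %in% c("S", "G2M")),
              all(unlist(lapply(phase_programs, names)) %in% genes))
  }
  if (!is.null(correlated_pairs)) {
    correlated_pairs <- tibble::as_tibble(correlated_pairs)
    stopifnot(all(c("gene_a", "gene_b", "rho") %in% names(correlated_pairs)),
              all(correlated_pairs$gene_a %in% genes),
              all(correlated_pairs$gene_b %in% genes),
              all(abs(correlated_pairs$rho) <= 1))
  }
  structure(list(populations = populations,
                 n_cells = rep_len(n_cells, length(populations)),
                 nb_dispersion = nb_dispersion,
                 dropout_rate = dropout_rate,
                 library_size_spread = library_size_spread,
                 correlated_pairs = correlated_pairs,
                 cellcycle_fraction = cellcycle_fraction,
                 cellcycle_strength = cellcycle_strength,
                 phase_programs = phase_programs,
                 mean_dependent_dropout = mean_dependent_dropout,
                 seed = seed),
            class = "sim_spec")
}

#' Simulate a single-cell counts matrix with planted structure
#'
#' Draws counts gene-by-cell from a negative binomial whose mean is the
#' population program scaled by a lognormal library size factor and the
#' cell-cycle program; planted gene pairs are coupled through a Gaussian
#' copula; independent Bernoulli dropout is applied last. Both the
#' observed (post-dropout) and the truth (pre-dropout) matrices are
#' returned, with the population labels and phases in `$obs`.
#'
#' @param spec a `sim_spec`.
#' @return List with `observed` (raw `expr_matrix` after dropout), `truth`
#'   (raw `expr_matrix` before dropout), and `labels` (tibble `cell`,
#'   `population`, `phase`).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  genes <- names(spec$populations[[1]])
  pops <- names(spec$populations)
  n_tot <- sum(spec$n_cells)
  with_seed(spec$seed, {
    population <- rep(pops, spec$n_cells)
    cells <- sprintf("cell_%04d", seq_len(n_tot))
    lib <- rlnorm(n_tot, meanlog = 0, sdlog = spec$library_size_spread)
    mu <- vapply(seq_len(n_tot), function(cix) {
      spec$populations[[population[cix]]][genes] * lib[cix]
    }, numeric(length(genes)))
    rownames(mu) <- genes

    phase <- rep("G1", n_tot)
    if (!is.null(spec$cellcycle_fraction)) {
      phase <- sample(names(spec$cellcycle_fraction), n_tot, replace = TRUE,
                      prob = spec$cellcycle_fraction)
      s_sig <- grep("^SSIG", genes, value = TRUE)
      g2m_sig <- grep("^G2MSIG", genes, value = TRUE)
      st <- spec$cellcycle_strength
      if (length(s_sig)) mu[s_sig, phase == "S"] <- mu[s_sig, phase == "S"] * st
      if (length(g2m_sig)) mu[g2m_sig, phase == "G2M"] <- mu[g2m_sig, phase == "G2M"] * st
      for (ph in names(spec$phase_programs)) {
        prog <- spec$phase_programs[[ph]]
        mu[names(prog), phase == ph] <- mu[names(prog), phase == ph] * prog
      }
    }

    truth <- matrix(rnbinom(length(mu), mu = mu, size = spec$nb_dispersion),
                    nrow = nrow(mu), dimnames = list(genes, cells))

    # planted co-regulation: a Gaussian copula on the negative binomial
    # margins; the copula correlation 2*sin(pi*rho/6) makes the Spearman
    # correlation of the pair equal rho (up to discreteness ties), without
    # touching the genes' means
    if (!is.null(spec$correlated_pairs)) {
      for (i in seq_len(nrow(spec$correlated_pairs))) {
        rho <- spec$correlated_pairs$rho[i]
        ga <- spec$correlated_pairs$gene_a[i]
        gb <- spec$correlated_pairs$gene_b[i]
        r <- 2 * sin(pi * rho / 6)
        z <- rnorm(n_tot)
        za <- z
        zb <- r * z + sqrt(1 - r^2) * rnorm(n_tot)
        truth[ga, ] <- stats::qnbinom(stats::pnorm(za), mu = mu[ga, ],
                                      size = spec$nb_dispersion)
        truth[gb, ] <- stats::qnbinom(stats::pnorm(zb), mu = mu[gb, ],
                                      size = spec$nb_dispersion)
      }
    }
    keep_prob <- if (spec$mean_dependent_dropout) {
      # logistic in log-mean, centred so the average dropout matches the rate
      p <- 1 / (1 + exp(-(log1p(mu) - stats::median(log1p(mu)))))
      1 - spec$dropout_rate * 2 * (1 - p)
    } else {
      matrix(1 - spec$dropout_rate, nrow(mu), ncol(mu))
    }
    keep <- matrix(rbinom(length(mu), 1, pmin(pmax(keep_prob, 0), 1)),
                   nrow = nrow(mu))
    observed <- truth * keep

    labels <- tibble::tibble(cell = cells, population = population, phase = phase)
    list(
      observed = expr_matrix(observed, layer = "raw", obs = labels),
      truth = expr_matrix(truth, layer = "raw", obs = labels),
      labels = labels
    )
  })
}

#' Default two-population fixture specification for a toy model
#'
#' Builds a `sim_spec` whose gene namespace is the toy model's GPR genes
#' plus decoy (non-metabolic) genes, cell-cycle signature genes, and one
#' planted co-regulated pair. Population `B` upshifts the genes of the
#' branched model's main route to biomass (transporters, upper glycolysis,
#' respiration: `G1`, `G2`, `G3`, `G9`, `G10`, `G11`) fivefold, planting a
#' metabolic difference that propagates to RAS, bounds, fluxes, and finally
#' cluster structure.
#'
#' @param model a toy `metabolic_model` (for the gene namespace).
#' @param n_cells cells per population (default 100).
#' @param dropout_rate see [sim_spec()] (default 0.4).
#' @param n_decoys number of decoy genes (default 60).
#' @param seed RNG seed.
#' @return A `sim_spec`.
#' @export
default_sim_spec <- function(model, n_cells = 100, dropout_rate = 0.4,
                             n_decoys = 200, seed = 0) {
  mg <- model_genes(model)
  decoys <- sprintf("DECOY%03d", seq_len(n_decoys))
  sgenes <- sprintf("SSIG%02d", 1:10)
  g2mgenes <- sprintf("G2MSIG%02d", 1:10)
  corgenes <- c("CORA", "CORB")
  clash <- intersect(mg, c(decoys, sgenes, g2mgenes, corgenes))
  if (length(clash)) {
    stop_scflux(sprintf("decoy gene names collide with model genes: %s",
                        paste(clash, collapse = ", ")),
                class = "scflux_config_error")
  }
  genes <- c(mg, decoys, sgenes, g2mgenes, corgenes)
  base <- stats::setNames(rep(50, length(genes)), genes)
  base[decoys] <- rep(c(5, 20, 80), length.out = n_decoys)
  base[c(sgenes, g2mgenes)] <- 10
  base[corgenes] <- 30
  pop_a <- base
  pop_b <- base
  trunk <- intersect(c("G1", "G2", "G3", "G9", "G10", "G11"), mg)
  pop_b[trunk] <- pop_b[trunk] * 5
  # distinct cell types differ beyond metabolism: give B its own broad decoy
  # program (real subpopulations differ in hundreds of genes), so that
  # neighbourhood graphs (denoising, clustering) can resolve the populations
  # under heavy dropout
  n_prog <- min(40L, n_decoys %/% 2L)
  prog_up <- decoys[seq_len(n_prog)]
  prog_dn <- decoys[n_prog + seq_len(n_prog)]
  pop_b[prog_up] <- pop_b[prog_up] * 6
  pop_b[prog_dn] <- pop_b[prog_dn] / 6
  sim_spec(
    populations = list(A = pop_a, B = pop_b),
    n_cells = n_cells,
    dropout_rate = dropout_rate,
    correlated_pairs = tibble::tibble(gene_a = "CORA", gene_b = "CORB", rho = 0.8),
    cellcycle_fraction = c(G1 = 0.6, S = 0.2, G2M = 0.2),
    cellcycle_strength = 3,
    # cycling cells synthesise biomass faster: mild boost of the growth route
    phase_programs = list(S = setNames(rep(1.3, length(trunk)), trunk),
                          G2M = setNames(rep(1.5, length(trunk)), trunk)),
    seed = seed
  )
}

#' Bundle a toy model with a matching simulated dataset
#'
#' Convenience fixture: a toy model preset plus simulated counts whose gene
#' namespace covers the model's GPR genes (with decoys), sufficient input
#' for the whole pipeline.
#'
#' @param preset toy model preset name (see [make_toy_model()]).
#' @param spec optional `sim_spec`; defaults to [default_sim_spec()] for the
#'   preset.
#' @param ... passed to [default_sim_spec()] when `spec` is missing.
#' @return List with `model`, `counts` (observed `expr_matrix`), `truth`,
#'   `labels`, and `spec`.
#' @export
end_to_end_fixture <- function(preset = "branched", spec = NULL, ...) {
  model <- make_toy_model(preset)
  spec <- spec %||% default_sim_spec(model, ...)
  sim <- simulate_counts(spec)
  list(model = model, counts = sim$observed, truth = sim$truth,
       labels = sim$labels, spec = spec)
}
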