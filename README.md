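# scflux

Single-cell flux balance analysis with denoised Reaction Activity Scores.

`scflux` is for computational biologists who want to stratify a mixed cell
population by *metabolic phenotype* rather than by raw expression. It embeds
each cell's scRNA-seq profile into a constraint-based metabolic model,
extracts one optimal flux vector per cell by flux balance analysis (FBA),
and clusters cells on those fluxes — with graph-diffusion denoising as the
pre-processing step that keeps dropout (false zeros) from zeroing out
reactions essential for the objective.

## The method in brief

A metabolic model is the steady-state flux polytope
`{v : S v = 0, v_L ≤ v ≤ v_U}` over a stoichiometric matrix *S*
(*M* metabolites × *R* reactions). The chain from transcripts to clusters:

1. **RAS.** Each GPR-bearing reaction *j* gets a per-cell Reaction Activity
   Score by substituting transcript abundances into its gene–protein–reaction
   rule: minimum over AND (subunits), sum over OR (isoenzymes), standard
   precedence; a gene missing from the matrix drops out of its operator
   (`A AND NaN = A`, `A OR NaN = A`).
2. **Envelopes.** Flux variability analysis on the rich-medium model gives
   each reaction's feasible range `[F_l, F_u]` (no fraction-of-optimum
   constraint).
3. **Per-cell bounds.** With `rho = RAS / max_cell RAS` (0 for all-zero rows):
   plain strategy `U = F_u * rho`, `L = F_l * rho`; epsilon strategy
   `U = eps + (F_u − eps) * rho`, `L = −eps + (F_l + eps) * rho`
   (default `eps = 0.01`), leaving residual capacity at zero RAS.
4. **FBA per cell**, maximising the objective (e.g. biomass synthesis), with
   a parsimonious tiebreak (minimise total |flux| at the fixed optimum) so
   the reported vertex is unique and solver-stable.
5. **QC + clustering.** Cells with a zero RAS on any reaction essential for
   the objective are removed (their optima reflect dropout, not biology);
   surviving flux vectors are z-scored per reaction, PCA-reduced, and
   clustered with Leiden, selecting the PC count and resolution that
   maximise the silhouette.

Denoising (a MAGIC-style kNN diffusion, reimplemented here) can run on the
counts matrix before RAS computation or directly on the RAS matrix; both
arms and the undenoised baseline are first-class pipeline configurations.

## Worked example

Simulate a two-population dataset tied to the bundled branched toy network
(two parallel routes to the biomass precursor; population B carries the
glucose/respiration trunk at 5× with 40% dropout), then run the full
pipeline with counts-level denoising:

```r
library(scflux)

fx <- end_to_end_fixture("branched", n_cells = 100, seed = 1)
fx$model
#> <metabolic_model> 7 metabolites x 9 reactions
#>   objective: BIOMASS
#>   exchange reactions: 2; GPR-bearing reactions: 6; genes: 11

cfg <- pipeline_config(fx$model, fx$counts, outdir = tempfile(),
                       min_genes_per_cell = 10, min_cells_per_gene = 3,
                       denoise_stage = "on_counts", seed = 1)
res <- run_pipeline(cfg)

glance(res$ras)
#> # A tibble: 1 × 6
#>   n_reactions n_cells coverage n_dropped zero_fraction layer
#>         <int>   <int>    <dbl>     <int>         <dbl> <chr>
#> 1           6     200        1         0             0 denoised

res$clusters
#> <cluster_result> 200 cells in 2 clusters (n_pcs = 5, resolution = 0.05, silhouette = 0.663)

known <- fx$labels$population[match(names(res$clusters$labels), fx$labels$cell)]
compare_to_known_groups(res$clusters, known)
#> # A tibble: 1 × 3
#>     ari   nmi     n
#>   <dbl> <dbl> <int>
#> 1 0.960 0.929   200
```

Reading the numbers: after denoising, the RAS matrix has **zero** sparsity
(undenoised it is ~43% zeros and ~87% of cells fail the essential-reaction
QC), all 200 cells carry a positive biomass optimum, and flux-space Leiden
clustering recovers the two planted populations almost perfectly
(ARI 0.96). Rerunning with `denoise_stage = "none"` collapses to a single
uninformative cluster on the few surviving cells — the motivating failure
mode. Every run directory contains the RAS/bounds/flux matrices, sparsity
and QC reports, cluster labels, correlation diagnostics, a run-metadata
JSON, and a checksum manifest; identical configurations reproduce identical
checksums.

Models are read from a tabular TSV dialect, cobrapy-style JSON, or SBML
Level 3 with the fbc extension (`read_model()`); counts from 10x-style
MTX directories or dense CSV (`read_counts()`).

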