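Package: scflux
Title: Single-Cell Flux Balance Analysis with Denoised Reaction Activity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates single-cell RNA-seq profiles into constraint-based
    metabolic models. Transcript abundances are converted to Reaction Activity
    Scores (RAS) through gene-protein-reaction (GPR) rules (minimum over AND,
    sum over OR), RAS values rescale flux-variability envelopes into per-cell
    flux bounds (plain or epsilon strategy), and one optimal flux vector per
    cell is extracted by flux balance analysis with a parsimonious tiebreak.
    Cells are then clustered on their optimal fluxes with silhouette-driven
    model selection over Leiden hyper-parameters. A graph-diffusion denoiser
    removes putative false zeros from counts or RAS matrices before
    constraint building, and a negative-binomial simulator with planted
    subpopulations and dropout supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    pracma,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    boot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
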