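#' Build a deterministic toy metabolic model
#'
#' Small networks used as test fixtures and for end-to-end simulations.
#' Two presets are available:
#'
#' * `"chain3"` — a linear chain: one exchange (`EX_a`), one conversion
#'   (`CONV`, GPR `G1`) and the objective sink (`GROWTH`, GPR `G2`). Every
#'   reaction is essential for the objective. The exchange starts closed
#'   (`lower_bound = 0`); open it with [apply_rich_medium()].
#' * `"branched"` — glucose and oxygen uptake feeding pyruvate production
#'   through two parallel routes (a direct one and a two-step one), then
#'   respiration and a biomass sink. The GPR census is fixed by
#'   construction: 2 single-gene rules, 1 OR-only rule, 2 AND-only rules,
#'   1 complex rule (both operators). Knocking out either single parallel
#'   route leaves the objective feasible; the trunk (uptakes, transporters,
#'   respiration, biomass) is essential.
#'
#' @param preset `"chain3"` or `"branched"`.
#' @return A validated `metabolic_model`.
#' @export
make_toy_model <- function(preset = c("chain3", "branched")) {
  if (length(preset) != 1 || !preset %in% c("chain3", "branched")) {
    stop_scflux(sprintf("unknown toy-model preset: '%s'", paste(preset, collapse = ",")),
                class = "scflux_config_error")
  }
  switch(preset, chain3 = toy_chain3(), branched = toy_branched())
}

toy_chain3 <- function() {
  mets <- c("a", "b")
  rxns <- c("EX_a", "CONV", "GROWTH")
  S <- matrix(0, 2, 3, dimnames = list(mets, rxns))
  S["a", "EX_a"] <- -1           # uptake = negative exchange flux
  S["a", "CONV"] <- -1; S["b", "CONV"] <- 1
  S["b", "GROWTH"] <- -1
  metabolic_model(S,
                  lower_bounds = c(0, 0, 0),
                  upper_bounds = c(1000, 1000, 1000),
                  gpr = c("", "G1", "G2"),
                  exchange = c(TRUE, FALSE, FALSE),
                  objective = "GROWTH")
}

# GPR census (by construction): single = T_glc, T_o2; or_only = P_upper;
# and_only = R_B1, R_resp; complex = R_B2.
toy_branched <- function() {
  mets <- c("glc", "g6p", "inter", "pyr", "o2", "o2c", "atp")
  rxns <- c("EX_glc", "EX_o2", "T_glc", "T_o2",
            "P_upper", "R_B1", "R_B2", "R_resp", "BIOMASS")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["glc", "EX_glc"] <- -1
  S["o2", "EX_o2"] <- -1
  S["glc", "T_glc"] <- -1; S["g6p", "T_glc"] <- 1
  S["o2", "T_o2"] <- -1; S["o2c", "T_o2"] <- 1
  S["g6p", "P_upper"] <- -1; S["pyr", "P_upper"] <- 1
  S["g6p", "R_B1"] <- -1; S["inter", "R_B1"] <- 1
  S["inter", "R_B2"] <- -1; S["pyr", "R_B2"] <- 1
  S["pyr", "R_resp"] <- -1; S["o2c", "R_resp"] <- -1; S["atp", "R_resp"] <- 2
  S["pyr", "BIOMASS"] <- -1; S["atp", "BIOMASS"] <- -2
  gpr <- c("", "", "G1", "G9",
           "G2 or G3", "G4 and G5", "G6 or (G7 and G8)", "G10 and G11", "")
  metabolic_model(S,
                  lower_bounds = rep(0, length(rxns)),
                  upper_bounds = rep(1000, length(rxns)),
                  gpr = gpr,
                  exchange = c(TRUE, TRUE, rep(FALSE, 7)),
                  objective = "BIOMASS")
}

#' Open all exchange reactions to a rich in silico medium
#'
#' Makes every nutrient with a transporter available in effectively
#' unlimited quantity by setting the uptake-direction bound of every
#' exchange reaction to `-uptake_magnitude` (uptake is negative exchange
#' flux by convention). Secretion bounds and non-exchange reactions are
#' untouched. A finite magnitude keeps the linear programs bounded.
#'
#' The operation is idempotent.
#'
#' @param model a `metabolic_model`.
#' @param uptake_magnitude positive flux magnitude (default 1000).
#' @return The model with opened uptake bounds.
#' @export
apply_rich_medium <- function(model, uptake_magnitude = 1000) {
  stopifnot(uptake_magnitude > 0)
  if (!any(model$exchange)) {
    warn_scflux("model flags no exchange reactions; returned unchanged",
                class = "scflux_medium_warning")
    return(model)
  }
  model$lower_bounds[model$exchange] <- -uptake_magnitude
  validate_model(model)
  model
}
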