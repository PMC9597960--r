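#' Construct a constraint-based metabolic model
#'
#' A metabolic model is the container consumed by all flux computations:
#' a stoichiometric matrix `S` (metabolites x reactions), per-reaction flux
#' bounds, gene-protein-reaction (GPR) rule strings, exchange flags, and the
#' identifier of the objective reaction.
#'
#' @param S numeric matrix (or `Matrix`) of stoichiometric coefficients,
#'   metabolites in rows, reactions in columns. Dimnames are required unless
#'   `metabolites`/`reactions` are given.
#' @param lower_bounds,upper_bounds numeric vectors of per-reaction flux
#'   limits (flux units, e.g. mmol/gDW/h).
#' @param gpr character vector of GPR strings, one per reaction; reactions
#'   without a rule use `""`.
#' @param exchange logical vector flagging exchange reactions (reactions that
#'   connect the network to the environment). By the COBRA sign convention
#'   used throughout, negative exchange flux is uptake and positive flux is
#'   secretion.
#' @param objective identifier of the reaction maximised by flux balance
#'   analysis.
#' @param metabolites,reactions optional identifier vectors overriding the
#'   dimnames of `S`.
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(S, lower_bounds, upper_bounds, gpr = NULL,
                            exchange = NULL, objective,
                            metabolites = NULL, reactions = NULL) {
  S <- Matrix::Matrix(S, sparse = TRUE)
  if (!is.null(metabolites)) rownames(S) <- metabolites
  if (!is.null(reactions)) colnames(S) <- reactions
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop_scflux("S must carry metabolite and reaction identifiers",
                class = "scflux_validation_error")
  }
  r <- ncol(S)
  gpr <- gpr %||% rep("", r)
  exchange <- exchange %||% guess_exchange(S)
  m <- structure(
    list(
      S = S,
      metabolites = rownames(S),
      reactions = colnames(S),
      lower_bounds = stats::setNames(as.numeric(lower_bounds), colnames(S)[seq_along(lower_bounds)]),
      upper_bounds = stats::setNames(as.numeric(upper_bounds), colnames(S)[seq_along(upper_bounds)]),
      gpr = stats::setNames(as.character(gpr), colnames(S)[seq_along(gpr)]),
      exchange = stats::setNames(as.logical(exchange), colnames(S)[seq_along(exchange)]),
      objective = objective
    ),
    class = "metabolic_model"
  )
  validate_model(m)
}

# Heuristic used by readers that do not mark exchanges explicitly: a reaction
# touching exactly one metabolite exchanges matter with the environment.
guess_exchange <- function(S) {
  apply(as_dense(S) != 0, 2, sum) == 1
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: bound/GPR/flag vectors match the number
#' of S columns, bounds are ordered, and the objective is a known reaction.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly unchanged, if valid; otherwise an error of
#'   class `scflux_validation_error`.
#' @export
validate_model <- function(model) {
  r <- ncol(model$S)
  lens <- c(lower_bounds = length(model$lower_bounds),
            upper_bounds = length(model$upper_bounds),
            gpr = length(model$gpr),
            exchange = length(model$exchange))
  bad <- lens != r
  if (any(bad)) {
    stop_scflux(
      sprintf("model fields with length != %d reactions: %s",
              r, paste(names(lens)[bad], collapse = ", ")),
      class = "scflux_validation_error")
  }
  if (any(model$lower_bounds > model$upper_bounds)) {
    j <- which(model$lower_bounds > model$upper_bounds)[1]
    stop_scflux(sprintf("lower bound exceeds upper bound for reaction '%s'",
                        model$reactions[j]),
                class = "scflux_validation_error")
  }
  if (!model$objective %in% model$reactions) {
    stop_scflux(sprintf("objective reaction '%s' not in the model", model$objective),
                class = "scflux_validation_error")
  }
  if (anyDuplicated(model$reactions) || anyDuplicated(model$metabolites)) {
    stop_scflux("duplicate reaction or metabolite identifiers",
                class = "scflux_validation_error")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites x %d reactions\n",
              nrow(x$S), ncol(x$S)))
  cat(sprintf("  objective: %s\n", x$objective))
  cat(sprintf("  exchange reactions: %d; GPR-bearing reactions: %d; genes: %d\n",
              sum(x$exchange), sum(nzchar(x$gpr)), length(model_genes(x))))
  invisible(x)
}

#' Genes referenced by a model's GPR rules
#'
#' @param model a `metabolic_model`.
#' @return Character vector of distinct gene identifiers.
#' @export
model_genes <- function(model) {
  rules <- model$gpr[nzchar(model$gpr)]
  if (!length(rules)) return(character())
  sort(unique(unlist(lapply(rules, function(s) gpr_genes(parse_gpr(s))))))
}

## ---------------------------------------------------------------------------
## Readers / writers
## ---------------------------------------------------------------------------

#' Read a metabolic model
#'
#' Supports three dialects: `tabular` (a TSV with columns `reaction_id`,
#' `equation`, `lower_bound`, `upper_bound`, `gpr`, `is_exchange` and the
#' objective flagged with column `objective`), `json` (the cobrapy-style JSON
#' schema), and `sbml` (SBML Level 3 with the fbc package for GPRs, bounds
#' and objectives).
#'
#' Equations in the tabular dialect are written `2 a + b --> c`; metabolites
#' on the left carry negative stoichiometry. GPR strings are preserved
#' verbatim; reactions with no rule get the empty string.
#'
#' @param path file path.
#' @param dialect one of `"tabular"`, `"json"`, `"sbml"`. Guessed from the
#'   extension when missing.
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, dialect = c("tabular", "json", "sbml")) {
  if (!file.exists(path)) {
    stop_scflux(sprintf("model file not found: %s", path), class = "scflux_io_error")
  }
  if (length(dialect) > 1) {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, json = "json", xml = "sbml", sbml = "sbml", "tabular")
  }
  dialect <- match.arg(dialect, c("tabular", "json", "sbml"))
  switch(dialect,
         tabular = read_model_tabular(path),
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Write a metabolic model
#'
#' Inverse of [read_model()] for the `tabular` and `json` dialects; the
#' round-trip reproduces S, bounds and GPR strings exactly.
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @param dialect `"tabular"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("tabular", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "tabular") write_model_tabular(model, path) else write_model_json(model, path)
  invisible(path)
}

format_equation <- function(S, j) {
  col <- as_dense(S[, j, drop = FALSE])[, 1]
  lhs <- which(col < 0)
  rhs <- which(col > 0)
  term <- function(i) {
    coef <- abs(col[i])
    if (coef == 1) rownames(S)[i] else paste(format(coef, scientific = FALSE), rownames(S)[i])
  }
  paste(paste(vapply(lhs, term, ""), collapse = " + "),
        "-->",
        paste(vapply(rhs, term, ""), collapse = " + "))
}

parse_equation <- function(eq, rxn_id) {
  sides <- strsplit(eq, "-->", fixed = TRUE)[[1]]
  if (length(sides) != 2) {
    stop_scflux(sprintf("reaction '%s': equation lacks a single '-->'", rxn_id),
                class = "scflux_parse_error")
  }
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric()
    for (tm in terms) {
      parts <- strsplit(tm, "\\s+")[[1]]
      if (length(parts) == 1) {
        coef <- 1; met <- parts
      } else if (length(parts) == 2 && !is.na(suppressWarnings(as.numeric(parts[1])))) {
        coef <- as.numeric(parts[1]); met <- parts[2]
      } else {
        stop_scflux(sprintf("reaction '%s': cannot parse term '%s'", rxn_id, tm),
                    class = "scflux_parse_error")
      }
      out[met] <- (out[met] %||% 0) + sign * coef
      if (is.na(out[met])) out[met] <- sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  both <- intersect(names(lhs), names(rhs))
  for (m in both) lhs[m] <- lhs[m] + rhs[m]
  c(lhs, rhs[setdiff(names(rhs), both)])
}

read_model_tabular <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "")
  needed <- c("reaction_id", "equation", "lower_bound", "upper_bound", "gpr", "is_exchange")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_scflux(sprintf("tabular model lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")),
                class = "scflux_parse_error")
  }
  if (any(!stats::complete.cases(df[, c("lower_bound", "upper_bound")]))) {
    stop_scflux("tabular model: missing bounds for some reactions",
                class = "scflux_validation_error")
  }
  stoich <- lapply(seq_len(nrow(df)), function(i) parse_equation(df$equation[i], df$reaction_id[i]))
  mets <- sort(unique(unlist(lapply(stoich, names))))
  S <- matrix(0, length(mets), nrow(df), dimnames = list(mets, df$reaction_id))
  for (i in seq_along(stoich)) S[names(stoich[[i]]), i] <- stoich[[i]]
  obj <- if ("objective" %in% names(df)) df$reaction_id[which(as.logical(df$objective))[1]] else NA
  if (is.na(obj)) {
    stop_scflux("tabular model: no reaction flagged in the 'objective' column",
                class = "scflux_parse_error")
  }
  gpr <- df$gpr
  gpr[is.na(gpr)] <- ""
  metabolic_model(S, df$lower_bound, df$upper_bound, gpr = gpr,
                  exchange = as.logical(df$is_exchange), objective = obj)
}

write_model_tabular <- function(model, path) {
  df <- data.frame(
    reaction_id = model$reactions,
    equation = vapply(seq_along(model$reactions), function(j) format_equation(model$S, j), ""),
    lower_bound = model$lower_bounds,
    upper_bound = model$upper_bounds,
    gpr = model$gpr,
    is_exchange = model$exchange,
    objective = model$reactions == model$objective,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$reactions) || is.null(j$metabolites)) {
    stop_scflux("json model lacks 'reactions' or 'metabolites'", class = "scflux_parse_error")
  }
  mets <- vapply(j$metabolites, function(m) m$id, "")
  rxns <- vapply(j$reactions, function(r) r$id, "")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  gpr <- character(length(rxns))
  obj <- NA_character_
  for (i in seq_along(j$reactions)) {
    r <- j$reactions[[i]]
    for (m in names(r$metabolites)) {
      if (!m %in% mets) {
        stop_scflux(sprintf("reaction '%s' references unknown metabolite '%s'", r$id, m),
                    class = "scflux_parse_error")
      }
      S[m, i] <- as.numeric(r$metabolites[[m]])
    }
    lb[i] <- as.numeric(r$lower_bound)
    ub[i] <- as.numeric(r$upper_bound)
    gpr[i] <- r$gene_reaction_rule %||% ""
    if (!is.null(r$objective_coefficient) && as.numeric(r$objective_coefficient) != 0) obj <- r$id
  }
  exch <- vapply(j$reactions, function(r) isTRUE(r$is_exchange), logical(1))
  if (!any(exch)) exch <- guess_exchange(S)
  if (is.na(obj)) {
    stop_scflux("json model: no reaction with a nonzero objective_coefficient",
                class = "scflux_parse_error")
  }
  metabolic_model(S, lb, ub, gpr = gpr, exchange = exch, objective = obj)
}

write_model_json <- function(model, path) {
  rxns <- lapply(seq_along(model$reactions), function(jx) {
    col <- as_dense(model$S[, jx, drop = FALSE])[, 1]
    nz <- col[col != 0]
    list(
      id = model$reactions[jx],
      metabolites = as.list(nz),
      lower_bound = unname(model$lower_bounds[jx]),
      upper_bound = unname(model$upper_bounds[jx]),
      gene_reaction_rule = unname(model$gpr[jx]),
      is_exchange = unname(model$exchange[jx]),
      objective_coefficient = as.numeric(model$reactions[jx] == model$objective)
    )
  })
  out <- list(
    metabolites = lapply(model$metabolites, function(m) list(id = m)),
    reactions = rxns,
    genes = lapply(model_genes(model), function(g) list(id = g))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## Minimal SBML Level 3 + fbc reader (species, reactions, flux bounds as fbc
## parameters, gene-product associations, active objective). Written on xml2;
## covers the subset of SBML that constraint-based models use.
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop_scflux(
                    sprintf("cannot parse SBML: %s", conditionMessage(e)),
                    class = "scflux_parse_error"))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- xml2::xml_attr(sp, "id")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  glabel <- stats::setNames(xml2::xml_attr(gps, "label"), xml2::xml_attr(gps, "id"))

  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop_scflux("SBML model has no reactions", class = "scflux_parse_error")
  rxns <- xml2::xml_attr(rx, "id")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  gpr <- character(length(rxns))

  assoc_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- xml2::xml_attr(node, "geneProduct")
      lab <- unname(glabel[gid])
      return(if (length(lab) && !is.na(lab)) lab else gid)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, assoc_to_string, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  for (i in seq_along(rx)) {
    r <- rx[[i]]
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, sprintf("./s:%s/s:speciesReference", side), ns)
      sgn <- if (side == "listOfReactants") -1 else 1
      for (ref in refs) {
        m <- xml2::xml_attr(ref, "species")
        coef <- as.numeric(xml2::xml_attr(ref, "stoichiometry") %||% "1")
        if (is.na(coef)) coef <- 1
        if (!m %in% mets) {
          stop_scflux(sprintf("reaction '%s' references unknown species '%s'", rxns[i], m),
                      class = "scflux_parse_error")
        }
        S[m, i] <- S[m, i] + sgn * coef
      }
    }
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    lb[i] <- if (!is.na(lbp)) pval[[lbp]] else -1000
    ub[i] <- if (!is.na(ubp)) pval[[ubp]] else 1000
    ga <- xml2::xml_find_first(r, ".//*[local-name()='geneProductAssociation']")
    gpr[i] <- if (inherits(ga, "xml_missing")) "" else {
      root <- xml2::xml_children(ga)[[1]]
      s <- assoc_to_string(root)
      # strip one redundant outer parenthesis pair for readability
      sub("^\\((.*)\\)$", "\\1", s)
    }
  }

  objref <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (inherits(objref, "xml_missing")) {
    stop_scflux("SBML model: no fbc flux objective found", class = "scflux_parse_error")
  }
  obj <- xml2::xml_attr(objref, "reaction")
  bc <- stats::setNames(xml2::xml_attr(sp, "boundaryCondition") == "true", mets)
  bc[is.na(bc)] <- FALSE
  exch <- guess_exchange(S) | apply(as_dense(S) != 0, 2, function(z) any(bc[z]))
  metabolic_model(S, lb, ub, gpr = gpr, exchange = exch, objective = obj)
}
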