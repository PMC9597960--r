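#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR strings are boolean expressions over gene identifiers with the
#' operators `and`/`or` (case-insensitive) and parentheses. `and` binds
#' tighter than `or` (standard precedence); parentheses override. The parse
#' tree keeps the verbatim source string and is classified as
#' `"single"` (one gene, no operator), `"or_only"`, `"and_only"`, or
#' `"complex"` (both operators present).
#'
#' @param s a nonempty GPR string.
#' @return An object of class `gpr_rule`: a list with the expression `tree`
#'   (nested lists; leaves carry `gene`, internal nodes carry `op` and
#'   `children`), `source` (verbatim string), `genes` (distinct leaves) and
#'   `class` (the four-way classification).
#' @export
parse_gpr <- function(s) {
  if (!is.character(s) || length(s) != 1 || !nzchar(trimws(s))) {
    stop_scflux("GPR string must be a nonempty character scalar",
                class = "scflux_parse_error")
  }
  toks <- gpr_tokenize(s)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  tree <- gpr_parse_or(toks, st)
  if (st$i <= nrow(toks)) {
    stop_scflux(sprintf("GPR parse error at position %d: unexpected '%s'",
                        toks$pos[st$i], toks$text[st$i]),
                class = "scflux_parse_error")
  }
  genes <- sort(unique(gpr_genes_tree(tree)))
  structure(list(tree = tree, source = s, genes = genes,
                 class = gpr_classify_tree(tree)),
            class = "gpr_rule")
}

gpr_tokenize <- function(s) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, s)[[1]]
  if (m[1] == -1) {
    stop_scflux("GPR string contains no tokens", class = "scflux_parse_error")
  }
  text <- regmatches(s, gregexpr(pat, s))[[1]]
  type <- ifelse(text == "(", "lpar",
          ifelse(text == ")", "rpar",
          ifelse(tolower(text) == "and", "and",
          ifelse(tolower(text) == "or", "or", "gene"))))
  data.frame(text = text, type = type, pos = as.integer(m),
             stringsAsFactors = FALSE)
}

gpr_peek <- function(toks, st) if (st$i <= nrow(toks)) toks$type[st$i] else "eof"

gpr_parse_or <- function(toks, st) {
  children <- list(gpr_parse_and(toks, st))
  while (gpr_peek(toks, st) == "or") {
    st$i <- st$i + 1L
    children <- c(children, list(gpr_parse_and(toks, st)))
  }
  if (length(children) == 1) children[[1]] else list(op = "or", children = children)
}

gpr_parse_and <- function(toks, st) {
  children <- list(gpr_parse_atom(toks, st))
  while (gpr_peek(toks, st) == "and") {
    st$i <- st$i + 1L
    children <- c(children, list(gpr_parse_atom(toks, st)))
  }
  if (length(children) == 1) children[[1]] else list(op = "and", children = children)
}

gpr_parse_atom <- function(toks, st) {
  tp <- gpr_peek(toks, st)
  if (tp == "gene") {
    g <- toks$text[st$i]
    st$i <- st$i + 1L
    return(list(gene = g))
  }
  if (tp == "lpar") {
    open_pos <- toks$pos[st$i]
    st$i <- st$i + 1L
    node <- gpr_parse_or(toks, st)
    if (gpr_peek(toks, st) != "rpar") {
      stop_scflux(sprintf("GPR parse error: unbalanced '(' opened at position %d", open_pos),
                  class = "scflux_parse_error")
    }
    st$i <- st$i + 1L
    return(node)
  }
  pos <- if (st$i <= nrow(toks)) toks$pos[st$i] else nchar(toks$text[nrow(toks)]) + toks$pos[nrow(toks)]
  stop_scflux(sprintf("GPR parse error at position %d: expected gene or '('", pos),
              class = "scflux_parse_error")
}

gpr_genes_tree <- function(node) {
  if (!is.null(node$gene)) return(node$gene)
  unlist(lapply(node$children, gpr_genes_tree))
}

gpr_classify_tree <- function(tree) {
  ops <- gpr_ops_tree(tree)
  if (!length(ops)) return("single")
  if (all(ops == "or")) return("or_only")
  if (all(ops == "and")) return("and_only")
  "complex"
}

gpr_ops_tree <- function(node) {
  if (!is.null(node$gene)) return(character())
  c(node$op, unlist(lapply(node$children, gpr_ops_tree)))
}

#' Genes of a parsed GPR rule
#' @param rule a `gpr_rule`.
#' @return Character vector of distinct gene identifiers.
#' @export
gpr_genes <- function(rule) rule$genes

#' @export
print.gpr_rule <- function(x, ...) {
  cat(sprintf("<gpr_rule> [%s] %s\n", x$class, x$source))
  invisible(x)
}

#' Evaluate a GPR rule on expression values
#'
#' Computes the Reaction Activity Score semantics: an AND node takes the
#' minimum of its non-missing children (enzyme sub-units: the scarcest limits
#' the complex), an OR node the sum of its non-missing children (isoenzymes
#' add capacity). A gene absent from `expr` is missing (`NA`): `A and NA`
#' evaluates to `A`, `A or NA` to `A`, and a node whose children are all
#' missing is itself missing. A measured value of 0 is a number, not a
#' missing value.
#'
#' Vectorised: `expr` may map genes to equal-length numeric vectors (e.g.
#' one value per cell); the result has that length.
#'
#' @param rule a `gpr_rule` from [parse_gpr()].
#' @param expr named list or named numeric vector mapping gene identifiers to
#'   values; genes not named are treated as missing.
#' @return Numeric vector of scores (`NA` where every gene is missing).
#' @export
eval_gpr <- function(rule, expr) {
  if (is.numeric(expr)) expr <- as.list(expr)
  n <- if (length(expr)) max(vapply(expr, length, 1L)) else 1L
  eval_gpr_node(rule$tree, expr, n)
}

eval_gpr_node <- function(node, expr, n) {
  if (!is.null(node$gene)) {
    v <- expr[[node$gene]]
    if (is.null(v)) return(rep(NA_real_, n))
    return(rep_len(as.numeric(v), n))
  }
  vals <- lapply(node$children, eval_gpr_node, expr = expr, n = n)
  comb <- if (node$op == "and") pmin_na else psum_na
  Reduce(comb, vals)
}

# pairwise min/sum ignoring NA, but NA when both are NA
pmin_na <- function(a, b) ifelse(is.na(a), b, ifelse(is.na(b), a, pmin(a, b)))
psum_na <- function(a, b) ifelse(is.na(a), b, ifelse(is.na(b), a, a + b))
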