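## Internal helpers shared across modules.

# Consistent error/warning helpers so messages carry a class that tests can
# assert on without matching prose.
stop_scflux <- function(msg, class = "scflux_error", ...) {
  rlang::abort(msg, class = c(class, "scflux_error"), ...)
}

warn_scflux <- function(msg, class = "scflux_warning") {
  rlang::warn(msg, class = c(class, "scflux_warning"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dense numeric matrix from base or Matrix input.
as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Fraction of exact zeros in a numeric matrix.
zero_fraction <- function(m) {
  m <- as_dense(m)
  sum(m == 0) / length(m)
}
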