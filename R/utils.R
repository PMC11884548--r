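# internal argument checks shared across modules

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_bad_arg(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lower || x > upper)
    stop_bad_arg(sprintf("'%s' must be in [%g, %g]", name, lower, upper))
  invisible(x)
}

check_matrix <- function(x, name, square = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_bad_arg(sprintf("'%s' must be a numeric matrix", name))
  if (square && nrow(x) != ncol(x))
    stop_bad_arg(sprintf("'%s' must be square", name))
  invisible(x)
}

is_symmetric <- function(x, tol = 1e-8) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) <= tol
}

upper_tri_values <- function(m) m[upper.tri(m)]

next_pow2 <- function(n) 2^ceiling(log2(n))

# deterministic child seeds: small integers derived from a parent seed,
# kept well inside 32-bit range
child_seed <- function(seed, k) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(k) %% 10000L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}
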