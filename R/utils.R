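# Shared internal helpers: grid snapping, seeded evaluation, assertions.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers never perturb (or depend on) global state.
#' With `seed = NULL` the expression runs against the current RNG stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Snap to the 25 ms programming grid.
snap25_up <- function(x) 25 * ceiling(x / 25)
snap25_nearest <- function(x) 25 * round(x / 25)

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# Scalar finite-number check used by constructors.
chk_num <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("'%s' must be a single finite number", name)
  }
  if (x < min || x > max) {
    stop_invalid("'%s' = %g outside allowed range [%g, %g]", name, x, min, max)
  }
  invisible(as.numeric(x))
}

# Derive a distinct (stable) sub-seed from a base seed, kept below 2^31.
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}
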