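## Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#'
#' All stochastic operations in the package route their randomness through this
#' helper so that (i) a given seed yields bit-identical output and (ii) calling
#' a seeded generator never disturbs the caller's RNG stream.
#'
#' @param seed integer scalar seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Fixed arithmetic for deriving per-subject child seeds from a master seed.
# Kept below .Machine$integer.max so set.seed() always accepts the result.
child_seed <- function(master, index) {
  as.integer((as.double(master) * 10007 + index * 101) %% 2147483629)
}

# Column demean of a matrix (voxels x whatever): subtract each column's mean.
demean_cols <- function(m) {
  sweep(m, 2L, colMeans(m), "-")
}

# Population standard deviation (divide by n, not n - 1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  invisible(x)
}
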