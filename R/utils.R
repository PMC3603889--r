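#' @keywords internal
"_PACKAGE"

## Vacuum permeability over 4*pi, SI units (T m / A).
MU0_OVER_4PI <- 1e-7

## row-wise Euclidean norms of an n x 3 matrix
row_norms <- function(x) sqrt(rowSums(x * x))

## normalize rows to unit length; rows with zero norm left untouched
normalize_rows <- function(x) {
  nrm <- row_norms(x)
  ok <- nrm > 0
  x[ok, ] <- x[ok, , drop = FALSE] / nrm[ok]
  x
}

## cross product of the rows of two n x 3 matrices
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## symmetric positive-definite solve A^{-1} B via Cholesky
chol_solve <- function(A, B) {
  ch <- chol(A)
  backsolve(ch, backsolve(ch, B, transpose = TRUE))
}
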