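#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded helpers do not perturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Cholesky with escalating relative diagonal jitter; all PD factorizations in
# the package funnel through here so near-singular systems fail gracefully.
safeChol <- function(A, label = "matrix") {
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(R)) return(R)
  scale <- mean(diag(A))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  jit <- 1e-10 * scale
  for (i in 1:8) {
    R <- tryCatch(chol(A + diag(jit, nrow(A))), error = function(e) NULL)
    if (!is.null(R)) {
      message("safeChol: added diagonal jitter ", format(jit), " to ", label)
      return(R)
    }
    jit <- jit * 100
  }
  stop("Cholesky factorization failed for ", label)
}

# Solve A x = b for symmetric positive-definite A.
symSolve <- function(A, b, label = "matrix") {
  R <- safeChol(A, label)
  backsolve(R, forwardsolve(t(R), b))
}

# Inverse of a symmetric positive-definite matrix.
symInverse <- function(A, label = "matrix") {
  chol2inv(safeChol(A, label))
}

#' First-order autoregressive (Toeplitz) correlation matrix
#'
#' Entry (i, j) is r^|i-j|; the intra-block correlation structure assumed by
#' the block prior and by the synthetic block-sparse generator.
#'
#' @param r Correlation coefficient in (-1, 1).
#' @param d Matrix dimension.
#' @return A d x d correlation matrix.
#' @export
toeplitzCorr <- function(r, d) {
  r^abs(outer(seq_len(d), seq_len(d), "-"))
}

colVars <- function(X) {
  n <- nrow(X)
  if (n == 0L) return(rep(NA_real_, ncol(X)))
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}
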