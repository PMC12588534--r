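#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means fixed-point iteration: memberships
#' u_ik = 1 / sum_k' (||x_i - c_k|| / ||x_i - c_k'||)^(2/(m-1)), centres
#' c_k = sum_i u_ik^m x_i / sum_i u_ik^m. Centres are initialized as K
#' distinct rows of `X` drawn under `seed`, and iteration stops when the
#' maximum centre shift drops below `tol` or `maxIter` is reached. With a
#' fixed seed the result is bit-reproducible. Points coinciding exactly with
#' a centre receive membership split evenly over the coinciding centres.
#'
#' @param X N x d feature matrix.
#' @param K Number of clusters (rules), 1 <= K <= N.
#' @param m Fuzziness exponent (> 1; default 2).
#' @param tol Convergence tolerance on the max absolute centre shift.
#' @param maxIter Maximum iterations.
#' @param seed Integer seed for the centre initialization.
#' @return An [FcmResult-class].
#' @export
fuzzyCMeans <- function(X, K, m = 2, tol = 1e-6, maxIter = 300L, seed = 1L) {
  X <- as.matrix(X)
  N <- nrow(X)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > N) stop("K = ", K, " exceeds the number of samples N = ", N)
  if (m <= 1) stop("fuzziness exponent m must be > 1")
  centers <- withSeed(seed, X[sample.int(N, K), , drop = FALSE])
  if (K > 1L && anyDuplicated(centers)) {
    warning("degenerate data: duplicated initial centers (identical rows)")
  }
  expo <- 2 / (m - 1)
  converged <- FALSE
  iter <- 0L
  u <- NULL
  for (iter in seq_len(maxIter)) {
    # squared distances N x K
    d2 <- outer(rowSums(X^2), rep(1, K)) - 2 * X %*% t(centers) +
      outer(rep(1, N), rowSums(centers^2))
    d2[d2 < 0] <- 0
    zero <- d2 == 0
    w <- d2^(-expo / 2)
    u <- w / rowSums(w)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    um <- u^m
    newCenters <- crossprod(um, X) / colSums(um)
    shift <- max(abs(newCenters - centers))
    centers <- newCenters
    if (shift < tol) { converged <- TRUE; break }
  }
  if (K > 1L && anyDuplicated(centers)) {
    warning("fuzzy c-means converged with tied centers")
  }
  methods::new("FcmResult", memberships = u, centers = centers,
               iterations = iter, converged = converged)
}

#' Estimate Gaussian rule antecedents from a clustering
#'
#' Rule centres are the membership-weighted feature means
#' c_jk = sum_i u_ik x_ij / sum_i u_ik and widths are h times the
#' membership-weighted squared deviations
#' delta_jk = h sum_i u_ik (x_ij - c_jk)^2 / sum_i u_ik, using the raw
#' (unexponentiated) memberships. Widths are floored at
#' 1e-8 * var_j + 1e-12 (var_j the population variance of feature j) so the
#' Gaussian membership stays defined when a cluster collapses onto a
#' constant feature.
#'
#' @param X N x d feature matrix the clustering was computed on.
#' @param fcm An [FcmResult-class].
#' @param h Width-scaling coefficient (> 0; default 1).
#' @return A [FuzzyAntecedent-class].
#' @export
estimateAntecedents <- function(X, fcm, h = 1) {
  if (h <= 0) stop("h must be positive")
  X <- as.matrix(X)
  u <- fcm@memberships
  if (nrow(u) != nrow(X)) stop("clustering and feature matrix disagree on N")
  wsum <- colSums(u)                       # length K
  centers <- crossprod(u, X) / wsum        # K x d
  K <- ncol(u)
  widths <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    dev2 <- sweep(X, 2, centers[k, ])^2
    widths[k, ] <- h * colSums(u[, k] * dev2) / wsum[k]
  }
  floorv <- 1e-8 * colVars(X) + 1e-12
  widths <- pmax(widths, matrix(floorv, K, ncol(X), byrow = TRUE))
  methods::new("FuzzyAntecedent", centers = centers, widths = widths, h = h)
}

#' Normalized rule firing strengths
#'
#' Per-feature Gaussian memberships exp(-(x_ij - c_jk)^2 / delta_jk) are
#' multiplied over features (the product t-norm) and normalized over rules.
#' Accumulation is done in the log domain with per-row max subtraction, so
#' the normalization cannot underflow to 0/0 even at large d.
#'
#' @param X N x d feature matrix.
#' @param A A [FuzzyAntecedent-class].
#' @return N x K matrix of normalized firing strengths; rows sum to 1.
#' @export
firingStrengths <- function(X, A) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite feature values")
  if (ncol(X) != ncol(A@centers)) {
    stop("feature dimension ", ncol(X), " does not match antecedent d = ",
         ncol(A@centers))
  }
  K <- nrow(A@centers)
  N <- nrow(X)
  logPhi <- matrix(0, N, K)
  for (k in seq_len(K)) {
    dev2 <- sweep(X, 2, A@centers[k, ])^2
    logPhi[, k] <- -rowSums(sweep(dev2, 2, A@widths[k, ], "/"))
  }
  mx <- apply(logPhi, 1, max)
  W <- exp(logPhi - mx)
  W / rowSums(W)
}

#' Build the fuzzy design matrix
#'
#' Row i concatenates, over rules k = 1..K, the block
#' firing_k(x_i) * (1, x_i), giving an N x ((1+d)K) matrix whose K
#' consecutive (1+d)-column blocks correspond to the rules. The sum of the K
#' intercept columns in any row equals 1 (the firing strengths normalize).
#'
#' @param X N x d feature matrix.
#' @param A A [FuzzyAntecedent-class].
#' @return A [FuzzyDesign-class].
#' @export
buildFuzzyDesign <- function(X, A) {
  X <- as.matrix(X)
  W <- firingStrengths(X, A)
  d <- ncol(X)
  K <- nrow(A@centers)
  Xe <- cbind(1, X)
  values <- matrix(0, nrow(X), (1L + d) * K)
  blockMap <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * (d + 1L) + 1L):(k * (d + 1L))
    values[, idx] <- W[, k] * Xe
    blockMap[[k]] <- idx
  }
  rownames(values) <- rownames(X)
  methods::new("FuzzyDesign", values = values, blockMap = blockMap,
               d = as.integer(d), K = as.integer(K))
}
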