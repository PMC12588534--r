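test_that("posterior mean reproduces the ridge closed form and limits", {
  set.seed(42)
  X <- matrix(rnorm(20 * 12), 20, 12)
  y <- rnorm(20)
  lam <- 0.5
  beta <- 3
  pm <- posteriorMoments(X, y, gamma = rep(1 / (lam * beta), 12), beta = beta)
  ridge <- drop(solve(crossprod(X) + lam * diag(12), crossprod(X, y)))
  expect_equal(pm$mu, ridge, tolerance = 1e-10)
  # and fitLs agrees with the same oracle
  ls <- fitLs(X, y, ridgeLambda = lam)
  expect_equal(ls@mu, ridge, tolerance = 1e-10)

  # noiseless limit: X = I, huge beta => mu -> y
  n <- 8
  pmI <- posteriorMoments(diag(n), y[1:n], gamma = rep(1, n), beta = 1e12)
  expect_lt(max(abs(pmI$mu - y[1:n])), 1e-6)

  # vanishing prior: mu -> 0
  pm0 <- posteriorMoments(X, y, gamma = rep(1e-12, 12), beta = beta)
  expect_lt(max(abs(pm0$mu)), 1e-8)
})

test_that("posterior matches a brute-force dense solve on random instances", {
  for (s in 1:50) {
    set.seed(s)
    N <- sample(5:40, 1)
    D <- sample(2:40, 1)
    X <- matrix(rnorm(N * D), N, D)
    y <- rnorm(N)
    # random block structure
    sizes <- withSeed(s, {
      out <- c()
      while (sum(out) < D) out <- c(out, sample(1:3, 1))
      out[length(out)] <- out[length(out)] - (sum(out) - D)
      out[out > 0]
    })
    ends <- cumsum(sizes)
    bm <- mapply(seq.int, ends - sizes + 1, ends, SIMPLIFY = FALSE)
    gamma <- runif(length(bm), 0.2, 3)
    beta <- runif(1, 0.5, 5)
    B <- lapply(sizes, function(d) toeplitzCorr(0.5, d))
    # brute force: explicit inverse of the primal precision
    Gm <- matrix(0, D, D)
    for (i in seq_along(bm)) Gm[bm[[i]], bm[[i]]] <- gamma[i] * B[[i]]
    Sigma <- solve(solve(Gm) + beta * crossprod(X))
    mu <- beta * drop(Sigma %*% crossprod(X, y))
    for (method in c("primal", "dual")) {
      pm <- posteriorMoments(X, y, gamma = gamma, beta = beta, B = B,
                             blockMap = bm, method = method)
      expect_equal(pm$mu, mu, tolerance = 1e-8)
      expect_equal(pm$Sigma, Sigma, tolerance = 1e-8, ignore_attr = TRUE)
    }
  }
})

test_that("evidence cost matches explicit log-det plus quadratic form", {
  # trivial identities: C = I via beta = 1, tiny gamma
  y0 <- rep(0, 6)
  X <- diag(6)
  expect_equal(bsblCost(X, y0, gamma = rep(1e-300, 6), beta = 1), 0,
               tolerance = 1e-10)
  y5 <- c(2, 1, 0, 0, 0, 0) # ||y||^2 = 5
  expect_equal(bsblCost(X, y5, gamma = rep(1e-300, 6), beta = 1), 5,
               tolerance = 1e-10)
  # random instances against naive determinant + solve
  for (s in 1:10) {
    set.seed(100 + s)
    N <- sample(5:30, 1)
    D <- sample(2:20, 1)
    X <- matrix(rnorm(N * D), N, D)
    y <- rnorm(N)
    gamma <- runif(D, 0.1, 2)
    beta <- runif(1, 0.5, 4)
    C <- diag(1 / beta, N) + X %*% diag(gamma, D) %*% t(X)
    naive <- as.numeric(determinant(C, logarithm = TRUE)$modulus) +
      drop(t(y) %*% solve(C) %*% y)
    expect_equal(bsblCost(X, y, gamma = gamma, beta = beta), naive,
                 tolerance = 1e-8)
    # and the cheap identity used inside the EM agrees
    pm <- posteriorMoments(X, y, gamma = gamma, beta = beta)
    expect_equal(pm$cost, naive, tolerance = 1e-8)
  }
})

test_that("gamma update is a fixed point when mu = 0 and Sigma = gamma B", {
  sizes <- c(3, 3)
  bm <- list(1:3, 4:6)
  gamma <- c(0.7, 1.9)
  B <- list(toeplitzCorr(0.6, 3), toeplitzCorr(-0.3, 3))
  Sigma <- matrix(0, 6, 6)
  for (i in 1:2) Sigma[bm[[i]], bm[[i]]] <- gamma[i] * B[[i]]
  X <- withSeed(1, matrix(rnorm(12 * 6), 12, 6))
  upd <- updateHyperparameters(rep(0, 6), Sigma, X, rnorm(12), bm, B = B)
  expect_equal(upd$gamma, gamma, tolerance = 1e-12)
})

test_that("one EM step matches an independently expanded evaluation", {
  set.seed(5)
  N <- 12
  bm <- list(1:3, 4:6)
  X <- matrix(rnorm(N * 6), N, 6)
  y <- rnorm(N)
  mu <- rnorm(6)
  A <- matrix(rnorm(36), 6)
  Sigma <- crossprod(A) / 6
  B <- list(toeplitzCorr(0.4, 3), diag(3))
  opts <- bsblOptions(correlationConstraint = "none")
  upd <- updateHyperparameters(mu, Sigma, X, y, bm, B = B, options = opts)
  # scripted expansion of the printed updates
  for (i in 1:2) {
    ix <- bm[[i]]
    Ti <- Sigma[ix, ix] + mu[ix] %o% mu[ix]
    expect_equal(upd$gamma[i], sum(diag(solve(B[[i]]) %*% Ti)) / 3,
                 tolerance = 1e-12)
    expect_equal(upd$B[[i]], Ti / upd$gamma[i], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_equal(upd$beta,
               N / (sum((y - X %*% mu)^2) + sum(diag(Sigma %*% crossprod(X)))),
               tolerance = 1e-12)
  # unit-scaled constraint: same raw update rescaled to unit diagonal mean
  updU <- updateHyperparameters(mu, Sigma, X, y, bm, B = B,
                                options = bsblOptions(
                                  correlationConstraint = "unit-scaled"))
  for (i in 1:2) {
    expect_equal(mean(diag(updU$B[[i]])), 1, tolerance = 1e-12)
    expect_equal(updU$B[[i]] / updU$B[[i]][1, 2],
                 upd$B[[i]] / upd$B[[i]][1, 2], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # toeplitz constraint: every B becomes Toeplitz(r) with the pooled r
  updT <- updateHyperparameters(mu, Sigma, X, y, bm, B = B,
                                options = bsblOptions())
  expect_equal(updT$B[[1]], toeplitzCorr(updT$r, 3), ignore_attr = TRUE)
  expect_equal(updT$B[[2]], toeplitzCorr(updT$r, 3), ignore_attr = TRUE)
  # exact-fit sanity: residual term vanishes => beta = N / Tr[Sigma X'X]
  yfit <- drop(X %*% mu)
  updFit <- updateHyperparameters(mu, Sigma, X, yfit, bm, B = B, options = opts)
  expect_equal(updFit$beta, N / sum(diag(Sigma %*% crossprod(X))),
               tolerance = 1e-12)
})

test_that("scalar-block gamma update reduces to Sigma_ii + mu_i^2", {
  set.seed(6)
  X <- matrix(rnorm(30), 10, 3)
  mu <- rnorm(3)
  Sigma <- diag(runif(3, 0.1, 1))
  upd <- updateHyperparameters(mu, Sigma, X, rnorm(10), as.list(1:3))
  expect_equal(upd$gamma, diag(Sigma) + mu^2, tolerance = 1e-12)
})

test_that("fitBsbl handles degenerate targets and is row-order invariant", {
  set.seed(7)
  X <- matrix(rnorm(30 * 8), 30, 8)
  bm <- list(1:4, 5:8)
  # y = 0: mu = 0 and every gamma shrinks monotonically
  fit0 <- fitBsbl(X, rep(0, 30), bsblOptions(maxIter = 25), blockMap = bm)
  expect_equal(fit0@mu, rep(0, 8), tolerance = 1e-12)
  y <- rnorm(30)
  fit <- suppressMessages(fitBsbl(X, y, blockMap = bm))
  perm <- sample(30)
  fitP <- suppressMessages(fitBsbl(X[perm, ], y[perm], blockMap = bm))
  expect_equal(fit@mu, fitP@mu, tolerance = 1e-9)
})

test_that("gamma trajectory for y = 0 shrinks monotonically", {
  set.seed(8)
  X <- matrix(rnorm(20 * 6), 20, 6)
  gamma <- rep(1, 2)
  B <- list(diag(3), diag(3))
  beta <- 1
  bm <- list(1:3, 4:6)
  prev <- gamma
  for (it in 1:10) {
    pm <- posteriorMoments(X, rep(0, 20), gamma = prev, beta = beta, B = B,
                           blockMap = bm)
    upd <- updateHyperparameters(pm$mu, pm$Sigma, X, rep(0, 20), bm, B = B,
                                 options = bsblOptions(learnB = FALSE))
    expect_true(all(upd$gamma < prev))
    prev <- upd$gamma
    beta <- upd$beta
  }
})

test_that("all-singleton fitBsbl equals fitSbl bit for bit", {
  set.seed(9)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- drop(X[, 1:3] %*% c(2, -1, 1)) + rnorm(40, sd = 0.1)
  a <- suppressMessages(fitBsbl(X, y, blockMap = as.list(1:10)))
  b <- suppressMessages(fitSbl(X, y))
  expect_identical(a@mu, b@mu)
  expect_identical(a@gamma, b@gamma)
  expect_identical(a@beta, b@beta)
  expect_identical(a@costTrace, b@costTrace)
})

test_that("singleton-block run recovers the same support as fitSbl on size-1 truth", {
  pr <- genBlockSparse(80, 12, 1, 3, intraBlockR = 0, snrDb = 30, seed = 21)
  a <- suppressMessages(fitBsbl(pr$design, pr$y, blockMap = pr$blockMap))
  b <- suppressMessages(fitSbl(pr$design, pr$y))
  expect_equal(recoveredSupport(a), recoveredSupport(b))
  expect_equal(recoveredSupport(a), pr$activeBlocks)
})

test_that("ridge baseline honors its limits", {
  set.seed(10)
  X <- matrix(rnorm(36), 6, 6)
  y <- rnorm(6)
  # lambda = 0, square invertible X => exact interpolation
  expect_equal(fitLs(X, y, ridgeLambda = 0)@mu, drop(solve(X, y)),
               tolerance = 1e-8)
  # lambda -> infinity => coefficients -> 0
  expect_lt(max(abs(fitLs(X, y, ridgeLambda = 1e12)@mu)), 1e-6)
  # rank-deficient with lambda = 0 => minimum-norm solution (with message)
  Xr <- cbind(X[, 1:2], X[, 1] + X[, 2])
  expect_message(fitLs(Xr, y, ridgeLambda = 0), "minimum-norm")
  expect_error(fitLs(X, y, ridgeLambda = -1), "non-negative")
})

test_that("prediction scores follow the documented conventions", {
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- rep(c(1, -1), each = 10)
  fit <- suppressMessages(fitBsbl(X, y, blockMap = list(1:3, 4:6)))
  pred <- predictScores(fit, X)
  expect_equal(pred$label, ifelse(pred$score > 0, 1L, -1L))
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  # mu = 0 model: scores 0, probabilities 0.5, labels -1 (tie rule)
  fit0 <- fit
  fit0@mu <- rep(0, 6)
  p0 <- predictScores(fit0, X)
  expect_true(all(p0$score == 0))
  expect_equal(p0$probability, rep(0.5, 20))
  expect_true(all(p0$label == -1L))
  # scaling mu by c > 0 scales scores, keeps labels
  fit2 <- fit
  fit2@mu <- 3 * fit@mu
  p2 <- predictScores(fit2, X)
  expect_equal(p2$score, 3 * pred$score, tolerance = 1e-12)
  expect_identical(p2$label, pred$label)
  expect_error(predictScores(fit, X[, 1:3]), "width")
  # separable fixture scores give AUC 1 on the training set
  sep <- separableProblem()
  fsep <- suppressMessages(fitBsbl(sep$X, sep$y, blockMap = list(1:3)))
  msep <- classMetrics(sep$y, predictScores(fsep, sep$X)$score)
  expect_equal(unname(msep["AUC"]), 1)
})

test_that("evidence cost decreases over full runs on benign problems", {
  drops <- 0
  for (s in 1:10) {
    pr <- genBlockSparse(60, 8, 3, 2, 0.8, 20, seed = 30 + s)
    fit <- suppressMessages(fitBsbl(pr$design, pr$y, blockMap = pr$blockMap))
    ct <- fit@costTrace
    # allow tiny numerical wiggle; require overall descent
    if (all(diff(ct) < 1e-3 * pmax(abs(ct[-length(ct)]), 1)) &&
        ct[length(ct)] < ct[1]) {
      drops <- drops + 1
    }
  }
  expect_gte(drops, 9)
})

test_that("non-convergence is flagged, not raised", {
  pr <- genBlockSparse(50, 6, 3, 2, 0.9, 15, seed = 40)
  fit <- suppressMessages(
    fitBsbl(pr$design, pr$y, bsblOptions(eta = 1e-12, maxIter = 3),
            blockMap = pr$blockMap))
  expect_false(fit@converged)
  expect_equal(fit@iterations, 3L)
})
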