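#' Run configuration for the full pipeline
#'
#' Collects every tunable of the encoder, the fuzzy system and the learner
#' into one validated list, which is echoed into every model file and report
#' for reproducibility.
#'
#' @param windowLength Sequence window length in nt (default 41).
#' @param k K-mer order of the propensity encoder (default 5).
#' @param psnpMode `"difference"` (F+ - F-) or `"positive"` (F+ only).
#' @param pseudocount Additive pseudocount for the propensity table
#'   (default 0).
#' @param rules Number of fuzzy rules K (default 25).
#' @param fuzziness Fuzzy c-means exponent m (default 2).
#' @param h Width-scaling coefficient of the Gaussian memberships
#'   (default 1).
#' @param fcmTol,fcmMaxIter Fuzzy c-means stopping parameters.
#' @param learner `"bsbl"`, `"sbl"` or `"ls"`.
#' @param ridgeLambda Ridge penalty for the `"ls"` learner (default 1).
#' @param eta,maxIter,betaInitRule,correlationConstraint,pruneGamma Passed to
#'   [bsblOptions()].
#' @param folds Cross-validation folds (default 5).
#' @param seed Master seed (default 1).
#' @return A validated configuration list of class `RunConfig`.
#' @export
runConfig <- function(windowLength = 41L, k = 5L,
                      psnpMode = c("difference", "positive"),
                      pseudocount = 0,
                      rules = 25L, fuzziness = 2, h = 1,
                      fcmTol = 1e-6, fcmMaxIter = 300L,
                      learner = c("bsbl", "sbl", "ls"), ridgeLambda = 1,
                      eta = 1e-4, maxIter = 500L,
                      betaInitRule = c("signal-energy", "noise-variance"),
                      correlationConstraint = c("toeplitz", "none",
                                                "unit-scaled"),
                      pruneGamma = 1e-4,
                      folds = 5L, seed = 1L) {
  cfg <- list(
    windowLength = as.integer(windowLength), k = as.integer(k),
    psnpMode = match.arg(psnpMode), pseudocount = pseudocount,
    rules = as.integer(rules), fuzziness = fuzziness, h = h,
    fcmTol = fcmTol, fcmMaxIter = as.integer(fcmMaxIter),
    learner = match.arg(learner), ridgeLambda = ridgeLambda,
    eta = eta, maxIter = as.integer(maxIter),
    betaInitRule = match.arg(betaInitRule),
    correlationConstraint = match.arg(correlationConstraint),
    pruneGamma = pruneGamma,
    folds = as.integer(folds), seed = as.integer(seed))
  validateConfig(cfg)
}

validateConfig <- function(cfg) {
  stopifnot(cfg$windowLength >= 1L, cfg$k >= 1L, cfg$k <= cfg$windowLength,
            cfg$rules >= 1L, cfg$fuzziness > 1, cfg$h > 0,
            cfg$eta > 0, cfg$maxIter >= 1L, cfg$pruneGamma >= 0,
            cfg$ridgeLambda >= 0, cfg$folds >= 2L, cfg$pseudocount >= 0)
  structure(cfg, class = "RunConfig")
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the [runConfig()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(runConfig, raw)
}

configOptions <- function(cfg) {
  bsblOptions(eta = cfg$eta, maxIter = cfg$maxIter,
              betaInitRule = cfg$betaInitRule,
              correlationConstraint = cfg$correlationConstraint,
              pruneGamma = cfg$pruneGamma)
}

#' Train the full site-prediction pipeline
#'
#' Builds the propensity table from the training data, encodes the features,
#' places the fuzzy rule antecedents by seeded fuzzy c-means, lifts the
#' features into the fuzzy design matrix and fits the consequents with the
#' configured learner.
#'
#' @param ds A [SiteDataset-class] with both classes present.
#' @param config A [runConfig()] list.
#' @return A [TskSiteModel-class].
#' @export
trainSiteModel <- function(ds, config = runConfig()) {
  if (windowLength(ds) != config$windowLength) {
    stop("dataset window length ", windowLength(ds),
         " does not match config windowLength ", config$windowLength)
  }
  table <- buildPropensity(ds, k = config$k, mode = config$psnpMode,
                           pseudocount = config$pseudocount)
  X <- encodeDataset(ds, table)
  fcm <- fuzzyCMeans(X, K = config$rules, m = config$fuzziness,
                     tol = config$fcmTol, maxIter = config$fcmMaxIter,
                     seed = config$seed)
  A <- estimateAntecedents(X, fcm, h = config$h)
  design <- buildFuzzyDesign(X, A)
  y <- siteLabels(ds)
  fit <- switch(config$learner,
    bsbl = fitBsbl(design, y, configOptions(config)),
    sbl = fitSbl(design, y, configOptions(config)),
    ls = fitLs(design, y, ridgeLambda = config$ridgeLambda))
  methods::new("TskSiteModel", propensity = table, antecedent = A,
               fit = fit, config = unclass(config))
}

#' Score sequences with a trained pipeline model
#'
#' @param model A [TskSiteModel-class].
#' @param newdata A [SiteDataset-class], `RNAStringSet`, or FASTA path.
#' @return A data.frame with columns id, score, predictive_sd, probability,
#'   label (see [predictScores()]).
#' @export
predictSites <- function(model, newdata) {
  if (is.character(newdata) && length(newdata) == 1L &&
      file.exists(newdata)) {
    newdata <- readRnaFasta(newdata)
  }
  X <- encodeDataset(newdata, model@propensity)
  if (nrow(X) == 0L) {
    return(data.frame(id = character(0), score = numeric(0),
                      predictive_sd = numeric(0), probability = numeric(0),
                      label = integer(0), stringsAsFactors = FALSE))
  }
  design <- buildFuzzyDesign(X, model@antecedent)
  predictScores(model@fit, design)
}

#' @describeIn predictSites `predict` method for the pipeline model.
#' @param object A [TskSiteModel-class].
#' @param ... Ignored.
#' @export
setMethod("predict", "TskSiteModel", function(object, newdata, ...) {
  predictSites(object, newdata)
})

#' Serialize a trained pipeline model to a JSON file
#'
#' The file contains the window length and k-mer order, the inline
#' propensity table, the antecedent centres/widths, the posterior mean, the
#' block hyperparameters (gamma, the Toeplitz correlation r with block
#' sizes, beta), the posterior covariance over active columns, the fit
#' options and the package version — everything needed for bit-reproducible
#' prediction from the file plus a FASTA.
#'
#' @param model A [TskSiteModel-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTskModel <- function(model, path) {
  fit <- model@fit
  payload <- list(
    format = "bsblfs-model",
    version = as.character(utils::packageVersion("bsblfs")),
    config = model@config,
    propensity = list(
      k = model@propensity@k,
      windowLength = model@propensity@windowLength,
      mode = model@propensity@mode,
      pseudocount = model@propensity@pseudocount,
      kmers = rownames(model@propensity@scores),
      scores = model@propensity@scores),
    antecedent = list(centers = model@antecedent@centers,
                      widths = model@antecedent@widths,
                      h = model@antecedent@h),
    fit = list(method = fit@method, mu = fit@mu, gamma = fit@gamma,
               corR = fit@corR, beta = fit@beta,
               blockSizes = unname(lengths(fit@blockMap)),
               activeCols = fit@activeCols, Sigma = fit@Sigma,
               iterations = fit@iterations, converged = fit@converged,
               options = fit@options))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a model serialized by [writeTskModel()]
#'
#' @param path Path to the JSON model file.
#' @return A [TskSiteModel-class].
#' @export
readTskModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "bsblfs-model")) {
    stop("not a bsblfs model file: ", path)
  }
  scores <- as.matrix(p$propensity$scores)
  rownames(scores) <- p$propensity$kmers
  colnames(scores) <- NULL
  table <- methods::new("PropensityTable",
    k = as.integer(p$propensity$k),
    windowLength = as.integer(p$propensity$windowLength),
    scores = scores, mode = p$propensity$mode,
    pseudocount = as.numeric(p$propensity$pseudocount))
  A <- methods::new("FuzzyAntecedent",
    centers = as.matrix(p$antecedent$centers),
    widths = as.matrix(p$antecedent$widths),
    h = as.numeric(p$antecedent$h))
  sizes <- as.integer(p$fit$blockSizes)
  ends <- cumsum(sizes)
  bm <- mapply(function(a, b) seq.int(a, b), ends - sizes + 1L, ends,
               SIMPLIFY = FALSE)
  corR <- p$fit$corR
  if (is.null(corR)) corR <- NA_real_
  beta <- p$fit$beta
  if (is.null(beta)) beta <- NA_real_
  B <- if (is.na(corR)) {
    lapply(sizes, function(d) diag(1, d))
  } else {
    lapply(sizes, function(d) toeplitzCorr(as.numeric(corR), d))
  }
  Sigma <- p$fit$Sigma
  Sigma <- if (is.null(Sigma) || !length(Sigma)) matrix(0, 0, 0) else as.matrix(Sigma)
  opts <- p$fit$options
  fit <- methods::new("BsblModel",
    mu = as.numeric(p$fit$mu),
    Sigma = Sigma,
    activeCols = as.integer(p$fit$activeCols),
    gamma = as.numeric(p$fit$gamma),
    B = B,
    corR = as.numeric(corR),
    beta = as.numeric(beta),
    blockMap = bm,
    iterations = as.integer(p$fit$iterations),
    converged = as.logical(p$fit$converged),
    costTrace = numeric(0),
    method = p$fit$method,
    options = as.list(opts))
  methods::new("TskSiteModel", propensity = table, antecedent = A, fit = fit,
               config = as.list(p$config))
}
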