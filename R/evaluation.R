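#' Confusion counts for +1/-1 labels
#'
#' @param labels True labels (+1/-1).
#' @param predicted Predicted labels (+1/-1).
#' @return Named integer vector TP, FP, TN, FN.
#' @export
confusionCounts <- function(labels, predicted) {
  if (length(labels) != length(predicted)) {
    stop("labels and predictions differ in length")
  }
  c(TP = sum(labels == 1 & predicted == 1),
    FP = sum(labels == -1 & predicted == 1),
    TN = sum(labels == -1 & predicted == -1),
    FN = sum(labels == 1 & predicted == -1))
}

# Rank-statistic AUC with half credit for ties; identical to the trapezoidal
# ROC area.
aucRank <- function(labels, scores) {
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == -1)
  if (nPos == 0 || nNeg == 0) return(NaN)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Classification metrics (SN, SP, ACC, MCC, AUC)
#'
#' Sensitivity SN = TP/(TP+FN), specificity SP = TN/(TN+FP), accuracy
#' ACC = (TP+TN)/N, Matthews correlation
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)) with the
#' convention MCC = 0 when any factor of the denominator vanishes, and AUC
#' by the rank statistic with half credit for tied scores. On a balanced
#' dataset ACC = (SN + SP) / 2 exactly.
#'
#' @param labels True labels (+1/-1).
#' @param scores Real-valued scores (larger = more positive).
#' @param threshold Decision threshold on the scores (default 0; a score
#'   equal to the threshold predicts -1).
#' @return Named numeric vector SN, SP, ACC, MCC, AUC. With single-class
#'   labels the undefined entries are NaN (with a warning).
#' @export
classMetrics <- function(labels, scores, threshold = 0) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  predicted <- ifelse(scores > threshold, 1L, -1L)
  cc <- as.numeric(confusionCounts(labels, predicted))
  names(cc) <- c("TP", "FP", "TN", "FN")
  TP <- cc["TP"]; FP <- cc["FP"]; TN <- cc["TN"]; FN <- cc["FN"]
  n <- sum(cc)
  if (TP + FN == 0 || TN + FP == 0) {
    warning("single-class labels: SN or SP undefined (NaN)")
  }
  SN <- if (TP + FN > 0) TP / (TP + FN) else NaN
  SP <- if (TN + FP > 0) TN / (TN + FP) else NaN
  ACC <- (TP + TN) / n
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  MCC <- if (denom > 0) (TP * TN - FP * FN) / sqrt(denom) else 0
  c(SN = unname(SN), SP = unname(SP), ACC = unname(ACC),
    MCC = unname(MCC), AUC = aucRank(labels, scores))
}

# Stratified fold assignment: within each class, a seeded shuffle is dealt
# round-robin into folds, preserving the class balance.
stratifiedFolds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  withSeed(seed, {
    for (cls in c(1L, -1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the dataset into class-stratified folds by a seeded shuffle. For
#' each fold, the propensity table, the fuzzy clustering/antecedents and the
#' consequent fit are computed from the training split only; metrics are
#' computed on the held-out fold. Reported summary metrics are the
#' unweighted mean over folds (macro); `pooled = TRUE` additionally reports
#' metrics over the pooled out-of-fold predictions (micro).
#'
#' @param ds A [SiteDataset-class] with both classes present.
#' @param config A [runConfig()] list.
#' @param folds Number of folds (default 5).
#' @param seed Fold-assignment seed (defaults to `config$seed`).
#' @param pooled Also compute micro (pooled-prediction) metrics.
#' @return A list with `perFold` (data.frame of fold, n, SN, SP, ACC, MCC,
#'   AUC), `mean` (macro averages) and optionally `pooled`.
#' @export
crossValidate <- function(ds, config = runConfig(), folds = 5L, seed = NULL,
                          pooled = FALSE) {
  y <- siteLabels(ds)
  if (min(sum(y == 1L), sum(y == -1L)) < folds) {
    stop("each class must have at least `folds` members")
  }
  if (is.null(seed)) seed <- config$seed
  fold <- stratifiedFolds(y, folds, seed)
  perFold <- vector("list", folds)
  poolScores <- numeric(length(y))
  for (f in seq_len(folds)) {
    trainDs <- ds[fold != f]
    testDs <- ds[fold == f]
    model <- trainSiteModel(trainDs, config)
    pred <- predictSites(model, testDs)
    met <- classMetrics(siteLabels(testDs), pred$score)
    perFold[[f]] <- data.frame(fold = f, n = length(testDs), t(met))
    poolScores[fold == f] <- pred$score
  }
  perFold <- do.call(rbind, perFold)
  out <- list(perFold = perFold,
              mean = colMeans(perFold[, c("SN", "SP", "ACC", "MCC", "AUC")]))
  if (pooled) out$pooled <- classMetrics(y, poolScores)
  out
}

#' Train on one dataset, evaluate on another
#'
#' Runs the full pipeline (propensity table, antecedents, consequent fit) on
#' the training dataset and evaluates once on the test dataset; used for
#' cross-species / cross-tissue protocols.
#'
#' @param trainDs,testDs [SiteDataset-class] objects with equal window
#'   length.
#' @param config A [runConfig()] list.
#' @return Named numeric vector SN, SP, ACC, MCC, AUC.
#' @export
crossDatasetEval <- function(trainDs, testDs, config = runConfig()) {
  if (windowLength(trainDs) != windowLength(testDs)) {
    stop("window lengths differ: ", windowLength(trainDs), " vs ",
         windowLength(testDs))
  }
  model <- trainSiteModel(trainDs, config)
  pred <- predictSites(model, testDs)
  classMetrics(siteLabels(testDs), pred$score)
}

#' All ordered train/test pairs of a dataset collection
#'
#' Evaluates [crossDatasetEval()] for every ordered pair of datasets and
#' returns a long-format (heat-map-ready) table.
#'
#' @param datasets Named list of [SiteDataset-class] objects.
#' @param config A [runConfig()] list.
#' @return data.frame with columns train, test, SN, SP, ACC, MCC, AUC.
#' @export
crossEvalMatrix <- function(datasets, config = runConfig()) {
  nm <- names(datasets)
  if (is.null(nm)) nm <- paste0("dataset", seq_along(datasets))
  rows <- list()
  for (i in seq_along(datasets)) {
    model <- trainSiteModel(datasets[[i]], config)
    for (j in seq_along(datasets)) {
      pred <- predictSites(model, datasets[[j]])
      met <- classMetrics(siteLabels(datasets[[j]]), pred$score)
      rows[[length(rows) + 1L]] <- data.frame(train = nm[i], test = nm[j],
                                              t(met))
    }
  }
  do.call(rbind, rows)
}

#' Write a per-fold metric report as a tidy TSV plus JSON summary
#'
#' @param report The list returned by [crossValidate()].
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @param dataset Dataset name recorded in the table.
#' @return Invisibly, the two paths.
#' @export
writeMetricReport <- function(report, prefix, dataset = "") {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  df <- cbind(dataset = dataset, report$perFold)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(dataset = dataset,
                            mean = as.list(report$mean),
                            pooled = if (!is.null(report$pooled))
                              as.list(report$pooled)),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
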