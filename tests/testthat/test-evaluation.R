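test_that("confusion counts match hand enumeration", {
  y <- rep(c(1L, -1L), each = 50)
  expect_equal(confusionCounts(y, y), c(TP = 50, FP = 0, TN = 50, FN = 0))
  allPos <- rep(1L, 100)
  expect_equal(confusionCounts(y, allPos)[["FP"]], 50)
  yh <- withSeed(1, sample(c(1L, -1L), 100, replace = TRUE))
  cc <- confusionCounts(y, yh)
  expect_equal(unname(cc["TP"]), sum(y == 1 & yh == 1))
  expect_equal(unname(cc["FN"]), sum(y == 1 & yh == -1))
  expect_equal(sum(cc), 100)
  expect_error(confusionCounts(y, yh[1:10]), "length")
})

test_that("MCC equals the Pearson correlation of the binary vectors", {
  for (s in 1:20) {
    y <- withSeed(s, sample(c(1, -1), 60, replace = TRUE))
    scores <- withSeed(100 + s, rnorm(60))
    if (length(unique(y)) < 2) next
    met <- classMetrics(y, scores)
    pred <- ifelse(scores > 0, 1, -1)
    oracle <- suppressWarnings(stats::cor(y, pred))
    if (is.na(oracle)) oracle <- 0 # constant predictions: MCC convention 0
    expect_equal(unname(met["MCC"]), oracle, tolerance = 1e-12)
  }
})

test_that("rank AUC equals the O(N^2) pairwise oracle with half-credit ties", {
  for (s in 1:5) {
    y <- withSeed(s, sample(c(1, -1), 200, replace = TRUE))
    scores <- withSeed(50 + s, round(rnorm(200), 1)) # rounding forces ties
    met <- classMetrics(y, scores)
    sp <- scores[y == 1]
    sn <- scores[y == -1]
    cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
    expect_equal(unname(met["AUC"]), mean(cmp), tolerance = 1e-12)
  }
  # perfectly separated scores
  y <- rep(c(1, -1), each = 10)
  s <- c(rnorm(10) + 10, rnorm(10) - 10)
  met <- classMetrics(y, s)
  expect_equal(unname(met["AUC"]), 1)
  expect_equal(unname(met["MCC"]), 1)
})

test_that("balanced-data accuracy identity holds, including the printed row", {
  # construct a balanced problem with SN = 0.9616, SP = 0.9468 at 4 decimals
  n <- 10000
  y <- rep(c(1, -1), each = n / 2)
  pred <- y
  pred[1:round(0.0384 * n / 2)] <- -1                 # SN = 1 - 0.0384
  pred[n / 2 + seq_len(round(0.0532 * n / 2))] <- 1   # SP = 1 - 0.0532
  scores <- pred * 0.5
  met <- classMetrics(y, scores)
  expect_equal(round(unname(met["SN"]), 4), 0.9616)
  expect_equal(round(unname(met["SP"]), 4), 0.9468)
  expect_equal(round(unname(met["ACC"]), 4), 0.9542)
  expect_equal(unname(met["ACC"]), unname((met["SN"] + met["SP"]) / 2),
               tolerance = 1e-12)
})

test_that("single-class labels yield NaN SN/SP with a warning", {
  y <- rep(1, 10)
  expect_warning(met <- classMetrics(y, rnorm(10)), "single-class")
  expect_true(is.nan(met[["SP"]]))
  expect_error(classMetrics(y, c(rnorm(9), Inf)), "finite")
})

smallConfig <- function(seed = 1) {
  runConfig(windowLength = 21L, k = 2L, rules = 4L, maxIter = 60L,
            seed = seed)
}

smallMotif <- function(nPos = 40, nNeg = 40, seed = 1, ...) {
  genMotifDataset(nPos, nNeg, windowLength = 21L, motif = "GGACA",
                  motifStart = 9L, seed = seed, ...)
}

test_that("cross-validation folds partition the data and stay stratified", {
  ds <- smallMotif(seed = 2)
  y <- siteLabels(ds)
  fold <- bsblfs:::stratifiedFolds(y, 5L, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 80L)
  for (f in 1:5) {
    expect_equal(sum(fold == f & y == 1), 8)
    expect_equal(sum(fold == f & y == -1), 8)
  }
  report <- suppressWarnings(crossValidate(ds, smallConfig(), folds = 5))
  expect_equal(nrow(report$perFold), 5L)
  expect_equal(sum(report$perFold$n), 80L)
  expect_error(crossValidate(ds[c(1:3, 41:78)], smallConfig()),
               "at least")
})

test_that("label-permuted data scores at chance over seeds", {
  aucs <- numeric(6)
  for (s in 1:6) {
    ds <- smallMotif(nPos = 30, nNeg = 30, seed = s)
    yPerm <- withSeed(1000 + s, sample(siteLabels(ds)))
    dsPerm <- SiteDataset(sequences(ds), yPerm, windowLength(ds))
    cv <- suppressWarnings(crossValidate(dsPerm, smallConfig(s), folds = 3))
    aucs[s] <- cv$mean["AUC"]
  }
  expect_gt(mean(aucs), 0.38)
  expect_lt(mean(aucs), 0.62)
})

test_that("training-split quantities never see the held-out fold", {
  ds <- smallMotif(seed = 5)
  y <- siteLabels(ds)
  fold <- bsblfs:::stratifiedFolds(y, 5L, seed = smallConfig()$seed)
  trainDs <- ds[fold != 1]
  tabBefore <- buildPropensity(trainDs, k = 2)
  # corrupt the held-out fold completely
  seqs <- as.character(sequences(ds))
  seqs[fold == 1] <- vapply(seqs[fold == 1], function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, "")
  dsCorrupt <- SiteDataset(seqs, y, windowLength(ds))
  tabAfter <- buildPropensity(dsCorrupt[fold != 1], k = 2)
  expect_identical(tabBefore@scores, tabAfter@scores)
})

test_that("cross-dataset evaluation behaves like the protocol demands", {
  cfg <- smallConfig()
  dsA <- smallMotif(seed = 7)
  # train == test reproduces resubstitution metrics
  model <- suppressWarnings(trainSiteModel(dsA, cfg))
  resub <- classMetrics(siteLabels(dsA), predictSites(model, dsA)$score)
  crossSame <- suppressWarnings(crossDatasetEval(dsA, dsA, cfg))
  expect_equal(crossSame, resub, tolerance = 1e-12)
  # disjoint motifs: no transferable signal, AUC near chance
  dsB <- genMotifDataset(40, 40, windowLength = 21L, motif = "UUCGU",
                         motifStart = 3L, flankGcPos = 0.5,
                         flankGcNeg = 0.5, seed = 8)
  dsC <- genMotifDataset(40, 40, windowLength = 21L, motif = "AGGCC",
                         motifStart = 14L, flankGcPos = 0.5,
                         flankGcNeg = 0.5, seed = 9)
  met <- suppressWarnings(crossDatasetEval(dsB, dsC, cfg))
  expect_gt(unname(met["AUC"]), 0.3)
  expect_lt(unname(met["AUC"]), 0.7)
  # window-length mismatch is refused
  ds41 <- randomDataset(10, 41)
  expect_error(crossDatasetEval(dsA, ds41, cfg), "window length")
})

test_that("shared-motif datasets transfer their signal across datasets", {
  cfg <- smallConfig()
  dsA <- smallMotif(nPos = 60, nNeg = 60, seed = 10)
  dsB <- smallMotif(nPos = 60, nNeg = 60, seed = 11)
  cross <- suppressWarnings(crossDatasetEval(dsA, dsB, cfg))
  cvA <- suppressWarnings(crossValidate(dsA, cfg, folds = 3))
  expect_lt(abs(unname(cross["AUC"]) - unname(cvA$mean["AUC"])), 0.1)
})

test_that("metric reports serialize to tidy TSV plus JSON", {
  ds <- smallMotif(seed = 12)
  report <- suppressWarnings(crossValidate(ds, smallConfig(), folds = 3,
                                           pooled = TRUE))
  prefix <- tempfile()
  writeMetricReport(report, prefix, dataset = "toy")
  tsv <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(nrow(tsv), 3L)
  expect_true(all(c("dataset", "fold", "SN", "SP", "ACC", "MCC", "AUC")
                  %in% colnames(tsv)))
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  expect_equal(js$mean$ACC, unname(report$mean["ACC"]))
})
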