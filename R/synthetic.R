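#' Generate a block-sparse regression problem with known ground truth
#'
#' Design entries are i.i.d. standard normal. `kActive` of the `M` blocks
#' are chosen at random; their coefficients are drawn from a zero-mean
#' Gaussian with first-order autoregressive (Toeplitz) covariance of
#' correlation `intraBlockR`; all other coefficients are exactly zero. Noise
#' is i.i.d. Gaussian rescaled so the realized signal-to-noise ratio
#' 10 log10(||Xp||^2 / ||noise||^2) equals `snrDb` exactly; `snrDb = Inf`
#' means no noise. All randomness derives from `seed`.
#'
#' @param N Number of observations.
#' @param M Number of blocks.
#' @param blockSize Size of every block.
#' @param kActive Number of active blocks (0 <= kActive <= M).
#' @param intraBlockR Intra-block correlation of the active coefficients
#'   (default 0.9).
#' @param snrDb Signal-to-noise ratio in dB (default 25; `Inf` = noiseless).
#' @param seed Integer seed.
#' @return List of class `BlockSparseProblem`: design, y, pTrue,
#'   activeBlocks, blockMap, snrDb, intraBlockR, snrRealized.
#' @export
genBlockSparse <- function(N, M, blockSize, kActive, intraBlockR = 0.9,
                           snrDb = 25, seed = 1L) {
  if (kActive > M) stop("kActive must not exceed M")
  if (kActive == 0 && is.finite(snrDb)) {
    stop("finite SNR is infeasible with no active blocks (zero signal)")
  }
  D <- M * blockSize
  blockMapping <- split(seq_len(D), rep(seq_len(M), each = blockSize))
  out <- withSeed(seed, {
    X <- matrix(stats::rnorm(N * D), N, D)
    act <- if (kActive > 0) sort(sample.int(M, kActive)) else integer(0)
    p <- numeric(D)
    if (kActive > 0) {
      L <- chol(toeplitzCorr(intraBlockR, blockSize))
      for (i in act) {
        p[blockMapping[[i]]] <- drop(crossprod(L, stats::rnorm(blockSize)))
      }
    }
    signal <- drop(X %*% p)
    if (is.finite(snrDb)) {
      noise <- stats::rnorm(N)
      target <- sum(signal^2) / 10^(snrDb / 10)
      noise <- noise * sqrt(target / sum(noise^2))
    } else {
      noise <- numeric(N)
    }
    list(X = X, p = p, act = act, signal = signal, noise = noise)
  })
  y <- out$signal + out$noise
  realized <- if (sum(out$noise^2) > 0) {
    10 * log10(sum(out$signal^2) / sum(out$noise^2))
  } else {
    Inf
  }
  structure(list(design = out$X, y = y, pTrue = out$p,
                 activeBlocks = out$act, blockMap = blockMapping,
                 snrDb = snrDb, intraBlockR = intraBlockR,
                 snrRealized = realized),
            class = "BlockSparseProblem")
}

#' Write a block-sparse problem to plain matrix text files
#'
#' Emits `<prefix>_design.tsv`, `<prefix>_y.tsv` and `<prefix>_ptrue.tsv`
#' for cross-language oracle checks.
#'
#' @param problem A `BlockSparseProblem`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths.
#' @export
writeBlockSparse <- function(problem, prefix) {
  paths <- paste0(prefix, c("_design.tsv", "_y.tsv", "_ptrue.tsv"))
  utils::write.table(problem$design, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(problem$y, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(problem$pTrue, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

sampleBackground <- function(n, gc) {
  sample(c("A", "C", "G", "U"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a motif-enriched labelled sequence dataset
#'
#' Emulates the reported statistical structure of modification-site
#' benchmarks: balanced fixed-length windows centred on an adenosine in both
#' classes (negatives are unmodified adenosine sites), positives carrying a
#' consensus motif (default GGACA across positions 19-23, 1-based) with a
#' per-position fidelity and GC-rich flanks, negatives with AU-rich flanks.
#' The central A of the window is always forced in both classes. Background
#' composition is uniform modulated by the GC probability: P(G) = P(C) =
#' gc/2, P(A) = P(U) = (1-gc)/2. Deterministic under `seed`.
#'
#' @param nPos,nNeg Class sizes.
#' @param windowLength Window length in nt (default 41).
#' @param motif Motif string (default "GGACA").
#' @param motifStart 1-based start position of the motif window (default 19,
#'   placing GGACA on positions 19-23 of a 41-nt window with the methylated
#'   A at position 21).
#' @param flankGcPos,flankGcNeg GC probability of the positive / negative
#'   background (defaults 0.6 / 0.35).
#' @param motifFidelity Per-position probability that a positive carries the
#'   motif character (default 0.95; the central A is always forced).
#' @param seed Integer seed.
#' @param name Dataset name.
#' @return A [SiteDataset-class] (positives first).
#' @export
genMotifDataset <- function(nPos, nNeg, windowLength = 41L, motif = "GGACA",
                            motifStart = 19L, flankGcPos = 0.6,
                            flankGcNeg = 0.35, motifFidelity = 0.95,
                            seed = 1L, name = "synthetic") {
  L <- as.integer(windowLength)
  mlen <- nchar(motif)
  motifEnd <- motifStart + mlen - 1L
  if (motifStart < 1L || motifEnd > L) {
    stop("motif window ", motifStart, "-", motifEnd,
         " does not fit in a ", L, "-nt window")
  }
  stopifnot(flankGcPos >= 0, flankGcPos <= 1, flankGcNeg >= 0,
            flankGcNeg <= 1, motifFidelity >= 0, motifFidelity <= 1)
  center <- (L + 1L) %/% 2L
  motifChars <- strsplit(motif, "")[[1]]
  seqs <- withSeed(seed, {
    mkSeq <- function(positive) {
      gc <- if (positive) flankGcPos else flankGcNeg
      s <- sampleBackground(L, gc)
      if (positive) {
        for (j in seq_len(mlen)) {
          if (stats::runif(1) < motifFidelity) {
            s[motifStart + j - 1L] <- motifChars[j]
          }
        }
      }
      s[center] <- "A"
      paste(s, collapse = "")
    }
    c(vapply(seq_len(nPos), function(i) mkSeq(TRUE), ""),
      vapply(seq_len(nNeg), function(i) mkSeq(FALSE), ""))
  })
  names(seqs) <- c(sprintf("pos_%d", seq_len(nPos)),
                   sprintf("neg_%d", seq_len(nNeg)))
  SiteDataset(seqs, c(rep(1L, nPos), rep(-1L, nNeg)), L, name)
}

#' Named presets for the motif generator
#'
#' `"strong"`: motif fidelity 0.95, flank GC 0.6 (positives) vs 0.35
#' (negatives) — a clearly separable dataset. `"moderate"`: fidelity 0.8,
#' GC 0.5 vs 0.42. `"null"`: no motif enrichment (fidelity 0) and identical
#' background (GC 0.5) in both classes — no class signal by construction.
#'
#' @param preset One of `"strong"`, `"moderate"`, `"null"`.
#' @return Named list of [genMotifDataset()] arguments.
#' @export
motifPreset <- function(preset = c("strong", "moderate", "null")) {
  switch(match.arg(preset),
    strong = list(motifFidelity = 0.95, flankGcPos = 0.6, flankGcNeg = 0.35),
    moderate = list(motifFidelity = 0.8, flankGcPos = 0.5, flankGcNeg = 0.42),
    null = list(motifFidelity = 0, flankGcPos = 0.5, flankGcNeg = 0.5))
}
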