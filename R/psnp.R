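#' All k-mers over the RNA alphabet in lexicographic order
#'
#' @param k K-mer order.
#' @return Character vector of length 4^k, lexicographic over A < C < G < U.
#' @export
allKmers <- function(k) {
  b <- c("A", "C", "G", "U")
  do.call(paste0, rev(do.call(expand.grid,
                              c(rep(list(b), k), stringsAsFactors = FALSE))))
}

# Per-position k-mer count matrix (4^k x d) for a character vector of
# equal-length sequences; rows in lexicographic k-mer order.
positionKmerCounts <- function(seqs, k, L) {
  kmers <- allKmers(k)
  d <- L - k + 1L
  counts <- matrix(0, nrow = length(kmers), ncol = d, dimnames = list(kmers, NULL))
  for (j in seq_len(d)) {
    idx <- match(substr(seqs, j, j + k - 1L), kmers)
    tab <- tabulate(idx, nbins = length(kmers))
    counts[, j] <- tab
  }
  counts
}

#' Build a position-specific k-mer propensity table from a training split
#'
#' For each window position j and k-mer m, computes the relative frequency of
#' m at j among positive-class and negative-class training sequences. In
#' `"difference"` mode (default) the stored propensity is
#' F+(m, j) - F-(m, j); in `"positive"` mode it is F+(m, j) alone. With the
#' default pseudocount of 0, a k-mer unseen in both classes scores exactly 0.
#'
#' The table must be built from the training split only; the evaluation
#' module rebuilds it inside every cross-validation fold.
#'
#' @param train A [SiteDataset-class] with both classes present.
#' @param k K-mer order (default 5).
#' @param mode `"difference"` or `"positive"`.
#' @param pseudocount Additive pseudocount on the per-position k-mer counts
#'   (default 0).
#' @return A [PropensityTable-class].
#' @examples
#' ds <- SiteDataset(c(p = "GGACAUU", n = "AAUAAAA"), c(1, -1))
#' tab <- buildPropensity(ds, k = 3)
#' tab@scores["GGA", 1] # 1: seen in all positives, no negatives
#' @export
buildPropensity <- function(train, k = 5L,
                            mode = c("difference", "positive"),
                            pseudocount = 0) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  L <- windowLength(train)
  if (k > L) stop("k-mer order k = ", k, " exceeds window length ", L)
  y <- siteLabels(train)
  if (!any(y == 1L) || !any(y == -1L)) {
    stop("training set must contain both classes to build a propensity table")
  }
  seqs <- as.character(sequences(train))
  freq <- function(cls) {
    cnt <- positionKmerCounts(seqs[y == cls], k, L) + pseudocount
    sweep(cnt, 2, colSums(cnt), "/")
  }
  fPos <- freq(1L)
  scores <- if (mode == "difference") fPos - freq(-1L) else fPos
  methods::new("PropensityTable",
    k = k, windowLength = as.integer(L), scores = scores,
    mode = mode, pseudocount = pseudocount)
}

#' Encode one sequence window as a propensity feature vector
#'
#' Component j is the table score of the k-mer starting at position j, giving
#' a vector of length d = L - k + 1 (37 for a 41-nt window with k = 5). Pure
#' deterministic lookup.
#'
#' @param seq An `RNAString`, 1-element `RNAStringSet`, or character string.
#' @param table A [PropensityTable-class].
#' @return Numeric vector of length L - k + 1.
#' @export
encodeSequence <- function(seq, table) {
  s <- toupper(as.character(seq))
  if (length(s) != 1L) stop("encodeSequence expects a single sequence")
  if (nchar(s) != table@windowLength) {
    stop("sequence length ", nchar(s), " does not match table window length ",
         table@windowLength)
  }
  k <- table@k
  d <- table@windowLength - k + 1L
  km <- substring(s, seq_len(d), seq_len(d) + k - 1L)
  ridx <- match(km, rownames(table@scores))
  if (anyNA(ridx)) stop("sequence contains k-mers outside the ACGU alphabet")
  table@scores[cbind(ridx, seq_len(d))]
}

#' Encode a whole dataset as a feature matrix
#'
#' Row i is `encodeSequence()` applied to sequence i; row order is preserved
#' and rownames carry the sequence ids.
#'
#' @param ds A [SiteDataset-class] (or `RNAStringSet`).
#' @param table A [PropensityTable-class].
#' @return N x (L - k + 1) numeric matrix.
#' @export
encodeDataset <- function(ds, table) {
  seqs <- if (methods::is(ds, "SiteDataset")) sequences(ds) else ds
  s <- as.character(seqs)
  k <- table@k
  L <- table@windowLength
  d <- L - k + 1L
  X <- matrix(0, nrow = length(s), ncol = d,
              dimnames = list(names(seqs), NULL))
  if (!length(s)) return(X)
  bad <- which(nchar(s) != L)
  if (length(bad)) {
    stop("sequences with length != ", L, ": ",
         paste(utils::head(names(seqs)[bad], 10), collapse = ", "))
  }
  kmers <- rownames(table@scores)
  for (j in seq_len(d)) {
    ridx <- match(substr(s, j, j + k - 1L), kmers)
    if (anyNA(ridx)) {
      stop("non-ACGU k-mer at position ", j, " in: ",
           paste(utils::head(names(seqs)[is.na(ridx)], 10), collapse = ", "))
    }
    X[, j] <- table@scores[cbind(ridx, j)]
  }
  X
}

#' Write a propensity table to a tab-separated file
#'
#' Rows are k-mers (lexicographic), columns are window positions; the first
#' column holds the k-mer. The companion [readPropensityTable()] restores the
#' object.
#'
#' @param table A [PropensityTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePropensityTable <- function(table, path) {
  df <- data.frame(kmer = rownames(table@scores), table@scores,
                   check.names = FALSE)
  colnames(df) <- c("kmer", paste0("pos", seq_len(ncol(table@scores))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k=%d windowLength=%d mode=%s pseudocount=%.17g",
                     table@k, table@windowLength, table@mode,
                     table@pseudocount), con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a propensity table written by [writePropensityTable()]
#'
#' @param path Input path.
#' @return A [PropensityTable-class].
#' @export
readPropensityTable <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-zA-Z]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          colClasses = "character", check.names = FALSE)
  scores <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(scores) <- "double"
  rownames(scores) <- df$kmer
  colnames(scores) <- NULL
  methods::new("PropensityTable",
    k = as.integer(vals[["k"]]),
    windowLength = as.integer(vals[["windowLength"]]),
    scores = scores, mode = vals[["mode"]],
    pseudocount = as.numeric(vals[["pseudocount"]]))
}
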