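#' Read RNA sequence windows from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, uppercases the
#' residues and maps T to U, so DNA-alphabet files (the usual distribution
#' format of public modification benchmarks) are accepted. Record order is
#' preserved and the record id is the first whitespace-delimited token of the
#' header. Alphabet validation beyond T->U is deferred to
#' [loadSiteDataset()], so files can be read and inspected before strict
#' checking.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::RNAStringSet].
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ggact"), tf)
#' readRnaFasta(tf) # one 5-nt record, residues GGACU
#' @export
readRnaFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (!length(nonEmpty)) stop("empty FASTA file: ", path)
  first <- nonEmpty[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA (line ", first, " does not start with '>'): ", path)
  }
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("malformed FASTA file ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (!length(x)) stop("empty FASTA file: ", path)
  s <- chartr("Tt", "Uu", toupper(as.character(x)))
  ids <- vapply(strsplit(names(x), "[ \t]"), `[`, "", 1)
  Biostrings::RNAStringSet(stats::setNames(s, ids))
}

#' Write sequences to a FASTA file
#'
#' Writes one record per sequence, single-line residues, deterministic bytes.
#'
#' @param x A [SiteDataset-class], `RNAStringSet`, or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRnaFasta <- function(x, path) {
  if (methods::is(x, "SiteDataset")) x <- sequences(x)
  if (is.character(x)) x <- Biostrings::RNAStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 20000L)
  invisible(path)
}

#' Construct a labelled site dataset
#'
#' Low-level constructor validating sequences, labels and window length
#' (strict A/C/G/U alphabet; ambiguity codes such as N are rejected because
#' the propensity encoder has no slot for them).
#'
#' @param sequences `RNAStringSet` or named character vector.
#' @param labels Vector of +1/-1 labels.
#' @param windowLength Declared window length (nt); defaults to the width of
#'   the first sequence.
#' @param name Dataset name.
#' @return A [SiteDataset-class].
#' @export
SiteDataset <- function(sequences, labels, windowLength = NULL, name = "") {
  if (is.character(sequences)) sequences <- Biostrings::RNAStringSet(sequences)
  if (is.null(names(sequences)) && length(sequences)) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (is.null(windowLength)) {
    windowLength <- if (length(sequences)) Biostrings::width(sequences)[1] else 0L
  }
  methods::new("SiteDataset",
    sequences = sequences,
    labels = as.integer(labels),
    windowLength = as.integer(windowLength),
    name = as.character(name))
}

#' Load a paired positive/negative FASTA benchmark
#'
#' Reads a positive-class and a negative-class FASTA file (the usual layout
#' of modification-site benchmarks), labels them +1 and -1, and validates
#' every window against the declared length and the strict A/C/G/U alphabet.
#' Offending record ids are listed in the error.
#'
#' @param posPath FASTA of positive (modified-site) windows.
#' @param negPath FASTA of negative windows.
#' @param windowLength Expected window length in nt (default 41).
#' @param name Dataset name for reports.
#' @return A [SiteDataset-class] with positives first, in file order.
#' @export
loadSiteDataset <- function(posPath, negPath, windowLength = 41L, name = "") {
  pos <- readRnaFasta(posPath)
  neg <- readRnaFasta(negPath)
  seqs <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(-1L, length(neg)))
  w <- Biostrings::width(seqs)
  badLen <- names(seqs)[w != windowLength]
  badChr <- names(seqs)[grepl("[^ACGU]", as.character(seqs))]
  if (length(badLen) || length(badChr)) {
    parts <- character(0)
    if (length(badLen)) {
      parts <- c(parts, paste0("wrong length (expected ", windowLength, "): ",
                               paste(utils::head(badLen, 10), collapse = ", ")))
    }
    if (length(badChr)) {
      parts <- c(parts, paste0("non-ACGU characters in: ",
                               paste(utils::head(badChr, 10), collapse = ", ")))
    }
    stop("sequence validation failed; ", paste(parts, collapse = "; "))
  }
  SiteDataset(seqs, labels, windowLength, name)
}
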