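# Shared fixtures, generated in code at test time.

# Write a FASTA file from a named character vector; returns the path.
writeFastaLines <- function(seqs, path = tempfile(fileext = ".fa"),
                            wrap = NULL) {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[i]))
    s <- seqs[[i]]
    if (is.null(wrap)) {
      lines <- c(lines, s)
    } else {
      starts <- seq(1, nchar(s), by = wrap)
      lines <- c(lines, substring(s, starts, pmin(starts + wrap - 1, nchar(s))))
    }
  }
  writeLines(lines, path)
  path
}

# Random ACGU windows of length L as a named character vector.
randomWindows <- function(n, L, seed = 1, prefix = "s") {
  withSeed(seed, {
    out <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
    }, "")
    names(out) <- paste0(prefix, seq_len(n))
    out
  })
}

# A small balanced labelled dataset of random windows.
randomDataset <- function(n = 20, L = 41, seed = 1) {
  stopifnot(n %% 2 == 0)
  SiteDataset(randomWindows(n, L, seed), rep(c(1L, -1L), each = n / 2), L)
}

# A tiny linearly separable design for classification sanity checks.
separableProblem <- function(n = 40, seed = 3) {
  withSeed(seed, {
    y <- rep(c(1, -1), each = n / 2)
    X <- cbind(1, y * 2 + rnorm(n, sd = 0.1), rnorm(n))
    list(X = X, y = y)
  })
}
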