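#' @import methods
#' @importFrom stats pnorm rnorm var sd cor setNames
#' @importFrom utils write.table read.table head
NULL

#' Labelled fixed-length sequence dataset
#'
#' Container for fixed-length RNA sequence windows with binary site labels
#' (+1 = modified site, -1 = unmodified). Sequences are stored as an
#' [Biostrings::RNAStringSet]; every window has the same declared length and
#' a strict A/C/G/U alphabet.
#'
#' @slot sequences An `RNAStringSet` of equal-length windows.
#' @slot labels Integer vector of +1/-1, one per sequence.
#' @slot windowLength Declared window length in nt.
#' @slot name Dataset name (free text, used in reports).
#'
#' @seealso [loadSiteDataset()], [genMotifDataset()]
#' @export
setClass("SiteDataset",
  representation(
    sequences = "ANY",
    labels = "integer",
    windowLength = "integer",
    name = "character"
  )
)

setValidity("SiteDataset", function(object) {
  msg <- character(0)
  seqs <- object@sequences
  if (!methods::is(seqs, "XStringSet")) {
    return("sequences must be an RNAStringSet")
  }
  if (length(seqs) != length(object@labels)) {
    msg <- c(msg, "number of sequences and labels differ")
  }
  if (!all(object@labels %in% c(-1L, 1L))) {
    msg <- c(msg, "labels must be +1 or -1")
  }
  w <- Biostrings::width(seqs)
  if (length(w) && any(w != object@windowLength)) {
    bad <- names(seqs)[w != object@windowLength]
    msg <- c(msg, paste0("sequences not of declared window length ",
                         object@windowLength, ": ",
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (length(seqs)) {
    chars <- Biostrings::uniqueLetters(seqs)
    extra <- setdiff(chars, c("A", "C", "G", "U"))
    if (length(extra)) {
      hasBad <- Biostrings::vcountPattern(extra[1], seqs) > 0
      for (e in extra[-1]) hasBad <- hasBad | Biostrings::vcountPattern(e, seqs) > 0
      msg <- c(msg, paste0("non-ACGU characters (", paste(extra, collapse = ""),
                           ") in: ", paste(utils::head(names(seqs)[hasBad], 5),
                                           collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Position-specific k-mer propensity table
#'
#' Lookup table mapping each of the 4^k k-mers at each of the L-k+1 window
#' positions to a real-valued propensity. In `"difference"` mode (the default)
#' the score is the positive-class minus negative-class per-position k-mer
#' relative frequency; in `"positive"` mode it is the positive-class frequency
#' alone.
#'
#' @slot k K-mer order.
#' @slot windowLength Window length L (nt).
#' @slot scores 4^k x (L-k+1) matrix; rownames are k-mers in lexicographic
#'   order over A < C < G < U.
#' @slot mode `"difference"` or `"positive"`.
#' @slot pseudocount Additive pseudocount used when building the table.
#'
#' @seealso [buildPropensity()], [encodeSequence()]
#' @export
setClass("PropensityTable",
  representation(
    k = "integer",
    windowLength = "integer",
    scores = "matrix",
    mode = "character",
    pseudocount = "numeric"
  )
)

setValidity("PropensityTable", function(object) {
  msg <- character(0)
  if (nrow(object@scores) != 4L^object@k) {
    msg <- c(msg, sprintf("scores must have 4^k = %d rows", 4L^object@k))
  }
  d <- object@windowLength - object@k + 1L
  if (ncol(object@scores) != d) {
    msg <- c(msg, sprintf("scores must have L - k + 1 = %d columns", d))
  }
  if (!object@mode %in% c("difference", "positive")) {
    msg <- c(msg, "mode must be 'difference' or 'positive'")
  }
  if (any(!is.finite(object@scores))) msg <- c(msg, "non-finite scores")
  if (length(msg)) msg else TRUE
})

#' Fuzzy c-means clustering result
#'
#' @slot memberships N x K membership matrix; rows sum to 1.
#' @slot centers K x d cluster centre matrix.
#' @slot iterations Number of iterations run.
#' @slot converged Whether the centre-shift tolerance was met.
#' @export
setClass("FcmResult",
  representation(
    memberships = "matrix",
    centers = "matrix",
    iterations = "integer",
    converged = "logical"
  )
)

setValidity("FcmResult", function(object) {
  if (nrow(object@centers) < 1L) return("at least one cluster required")
  if (ncol(object@memberships) != nrow(object@centers)) {
    return("memberships and centers disagree on K")
  }
  rs <- rowSums(object@memberships)
  if (length(rs) && max(abs(rs - 1)) > 1e-8) {
    return("membership rows must sum to 1")
  }
  TRUE
})

#' TSK rule antecedents (Gaussian membership parameters)
#'
#' Per-rule, per-feature Gaussian membership centres and widths. The width
#' enters the membership as exp(-(x - c)^2 / delta), i.e. delta is a variance
#' scale, not a standard deviation.
#'
#' @slot centers K x d matrix of rule centres.
#' @slot widths K x d matrix of strictly positive widths (after flooring).
#' @slot h Width-scaling coefficient used when the widths were estimated.
#' @export
setClass("FuzzyAntecedent",
  representation(centers = "matrix", widths = "matrix", h = "numeric")
)

setValidity("FuzzyAntecedent", function(object) {
  if (!all(dim(object@centers) == dim(object@widths))) {
    return("centers and widths must have identical shape")
  }
  if (any(object@widths <= 0)) return("widths must be strictly positive")
  if (object@h <= 0) return("h must be positive")
  TRUE
})

#' Fuzzy design matrix (rule-lifted features)
#'
#' The N x ((1+d)K) matrix whose row i concatenates, over rules k, the
#' firing-strength-weighted extended input mu_k(x_i) * (1, x_i), together
#' with the map from rules to column blocks.
#'
#' @slot values N x ((1+d)K) numeric matrix.
#' @slot blockMap List of K integer index vectors, one (1+d)-column block per
#'   rule, partitioning the columns.
#' @slot d Feature dimension.
#' @slot K Rule count.
#' @export
setClass("FuzzyDesign",
  representation(values = "matrix", blockMap = "list",
                 d = "integer", K = "integer")
)

setValidity("FuzzyDesign", function(object) {
  idx <- unlist(object@blockMap, use.names = FALSE)
  if (!identical(sort(idx), seq_len(ncol(object@values)))) {
    return("blockMap must partition the design columns")
  }
  sizes <- lengths(object@blockMap)
  if (length(unique(sizes)) > 1L || sizes[1] != object@d + 1L) {
    return("each rule block must span 1+d columns")
  }
  if (length(object@blockMap) != object@K) return("blockMap length must be K")
  TRUE
})

#' Fitted consequent model (block-sparse Bayesian, sparse Bayesian, or ridge)
#'
#' Posterior mean/covariance of the TSK consequent vector together with the
#' learned hyperparameters. For the ridge least-squares baseline
#' (`method = "ls"`) only the point estimate is populated.
#'
#' @slot mu Posterior mean (length D = sum of block sizes); pruned blocks are 0.
#' @slot Sigma Posterior covariance over active columns (see `activeCols`);
#'   0 x 0 for `"ls"` fits.
#' @slot activeCols Integer indices of unpruned columns.
#' @slot gamma Per-block scale hyperparameters (0 for pruned blocks).
#' @slot B List of per-block correlation matrices (identity-scaled).
#' @slot corR Intra-block correlation coefficient of the Toeplitz constraint
#'   (NA when not constrained).
#' @slot beta Noise precision (NA for `"ls"`).
#' @slot blockMap List of column index vectors, one per block.
#' @slot iterations EM iterations run.
#' @slot converged Convergence flag.
#' @slot costTrace Per-iteration -2 log marginal likelihood values.
#' @slot method `"bsbl"`, `"sbl"` or `"ls"`.
#' @slot options The option list used for the fit.
#' @export
setClass("BsblModel",
  representation(
    mu = "numeric", Sigma = "matrix", activeCols = "integer",
    gamma = "numeric", B = "list", corR = "numeric", beta = "numeric",
    blockMap = "list", iterations = "integer", converged = "logical",
    costTrace = "numeric", method = "character", options = "list"
  )
)

setValidity("BsblModel", function(object) {
  if (!object@method %in% c("bsbl", "sbl", "ls")) {
    return("method must be bsbl, sbl or ls")
  }
  if (any(object@gamma < 0)) return("gamma must be non-negative")
  if (any(!is.finite(object@costTrace))) return("costTrace must be finite")
  TRUE
})

#' End-to-end trained site prediction model
#'
#' Bundles the propensity encoder, the fuzzy antecedents and the fitted
#' consequent model, plus the run configuration, so prediction needs only
#' this object (or its JSON serialization) and a FASTA file.
#'
#' @slot propensity A [PropensityTable-class].
#' @slot antecedent A [FuzzyAntecedent-class].
#' @slot fit A [BsblModel-class].
#' @slot config The [runConfig()] list used for training.
#' @export
setClass("TskSiteModel",
  representation(propensity = "PropensityTable",
                 antecedent = "FuzzyAntecedent",
                 fit = "BsblModel",
                 config = "list")
)
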