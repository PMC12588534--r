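#' @rdname SiteDataset-class
#' @param object,x A `SiteDataset`.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname SiteDataset-class
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname SiteDataset-class
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))

#' @rdname SiteDataset-class
#' @export
setGeneric("datasetName", function(x) standardGeneric("datasetName"))

#' @rdname FuzzyDesign-class
#' @param x Object with a design matrix.
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))

#' @rdname FuzzyDesign-class
#' @export
setGeneric("blockMap", function(x) standardGeneric("blockMap"))

#' Accessors ----------------------------------------------------------------

#' @rdname SiteDataset-class
#' @export
setMethod("sequences", "SiteDataset", function(x) x@sequences)

#' @rdname SiteDataset-class
#' @export
setMethod("siteLabels", "SiteDataset", function(x) x@labels)

#' @rdname SiteDataset-class
#' @export
setMethod("windowLength", "SiteDataset", function(x) x@windowLength)

#' @rdname SiteDataset-class
#' @export
setMethod("datasetName", "SiteDataset", function(x) x@name)

#' @rdname SiteDataset-class
#' @export
setMethod("length", "SiteDataset", function(x) length(x@sequences))

#' Subset a SiteDataset by index
#'
#' @param x A `SiteDataset`.
#' @param i Integer or logical index.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "SiteDataset", function(x, i, j, ..., drop = FALSE) {
  methods::new("SiteDataset",
    sequences = x@sequences[i],
    labels = x@labels[i],
    windowLength = x@windowLength,
    name = x@name)
})

#' @rdname FuzzyDesign-class
#' @export
setMethod("designMatrix", "FuzzyDesign", function(x) x@values)

#' @rdname FuzzyDesign-class
#' @export
setMethod("blockMap", "FuzzyDesign", function(x) x@blockMap)

#' @rdname BsblModel-class
#' @export
setMethod("blockMap", "BsblModel", function(x) x@blockMap)

#' Show methods --------------------------------------------------------------

setMethod("show", "SiteDataset", function(object) {
  n <- length(object@sequences)
  cat("SiteDataset", if (nzchar(object@name)) sQuote(object@name) else "",
      "\n  ", n, " sequences of ", object@windowLength, " nt (",
      sum(object@labels == 1L), " positive / ",
      sum(object@labels == -1L), " negative)\n", sep = "")
})

setMethod("show", "PropensityTable", function(object) {
  cat("PropensityTable: k = ", object@k, ", L = ", object@windowLength,
      " -> ", nrow(object@scores), " k-mers x ", ncol(object@scores),
      " positions (mode = ", object@mode, ")\n", sep = "")
})

setMethod("show", "FcmResult", function(object) {
  cat("FcmResult: K = ", nrow(object@centers), ", N = ",
      nrow(object@memberships), ", ", object@iterations, " iterations (",
      if (object@converged) "converged" else "not converged", ")\n", sep = "")
})

setMethod("show", "FuzzyAntecedent", function(object) {
  cat("FuzzyAntecedent: K = ", nrow(object@centers), " rules, d = ",
      ncol(object@centers), " features, h = ", object@h, "\n", sep = "")
})

setMethod("show", "FuzzyDesign", function(object) {
  cat("FuzzyDesign: ", nrow(object@values), " x ", ncol(object@values),
      " (", object@K, " rule blocks of ", object@d + 1L, ")\n", sep = "")
})

setMethod("show", "BsblModel", function(object) {
  act <- sum(object@gamma > 0)
  cat("BsblModel [", object@method, "]: ", length(object@mu),
      " coefficients in ", length(object@blockMap), " blocks",
      if (length(object@gamma)) paste0(" (", act, " active)") else "",
      "\n  iterations: ", object@iterations,
      ", converged: ", object@converged, "\n", sep = "")
})

setMethod("show", "TskSiteModel", function(object) {
  cat("TskSiteModel: L = ", object@propensity@windowLength,
      ", k = ", object@propensity@k,
      ", K = ", nrow(object@antecedent@centers),
      " rules, learner = ", object@fit@method, "\n", sep = "")
})
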