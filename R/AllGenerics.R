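#' @include AllClasses.R
NULL

#' @rdname GenePanel-accessors
#' @export
setGeneric("mmrGenes", function(x) standardGeneric("mmrGenes"))
#' @rdname GenePanel-accessors
#' @export
setGeneric("hypermutationGenes",
           function(x) standardGeneric("hypermutationGenes"))
#' @rdname GenePanel-accessors
#' @export
setGeneric("housekeepingGenes",
           function(x) standardGeneric("housekeepingGenes"))
#' @rdname GenePanel-accessors
#' @export
setGeneric("scoringGenes", function(x) standardGeneric("scoringGenes"))

#' @rdname ReferenceStats-accessors
#' @export
setGeneric("mmrMu", function(x) standardGeneric("mmrMu"))
#' @rdname ReferenceStats-accessors
#' @export
setGeneric("mmrSd", function(x) standardGeneric("mmrSd"))
#' @rdname ReferenceStats-accessors
#' @export
setGeneric("hyperWeights", function(x) standardGeneric("hyperWeights"))
#' @rdname ReferenceStats-accessors
#' @export
setGeneric("hyperMuMss", function(x) standardGeneric("hyperMuMss"))
#' @rdname ReferenceStats-accessors
#' @export
setGeneric("hyperSdMss", function(x) standardGeneric("hyperSdMss"))

#' @rdname MixtureFit-accessors
#' @export
setGeneric("mixtureMeans", function(x) standardGeneric("mixtureMeans"))
#' @rdname MixtureFit-accessors
#' @export
setGeneric("mixtureSds", function(x) standardGeneric("mixtureSds"))
#' @rdname MixtureFit-accessors
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))
#' @rdname MixtureFit-accessors
#' @export
setGeneric("bic", function(x) standardGeneric("bic"))

#' @rdname RocResult-accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname RocResult-accessors
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

# -- GenePanel ---------------------------------------------------------------

#' Accessors for GenePanel objects
#'
#' `mmrGenes()`, `hypermutationGenes()` and `housekeepingGenes()` return the
#' gene ids in each role; `scoringGenes()` returns the union of the 14 genes
#' (4 MMR + 10 signature) every score requires.
#'
#' @param x a [GenePanel-class] (or, for the stats accessors, a
#'   [ReferenceStats-class]).
#' @return a character vector of gene ids.
#' @name GenePanel-accessors
NULL

#' @rdname GenePanel-accessors
#' @export
setMethod("mmrGenes", "GenePanel", function(x) x@mmrGenes)
#' @rdname GenePanel-accessors
#' @export
setMethod("hypermutationGenes", "GenePanel", function(x) x@hypermutationGenes)
#' @rdname GenePanel-accessors
#' @export
setMethod("housekeepingGenes", "GenePanel", function(x) x@housekeepingGenes)
#' @rdname GenePanel-accessors
#' @export
setMethod("scoringGenes", "GenePanel",
          function(x) c(x@mmrGenes, x@hypermutationGenes))

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel\n")
  cat("  MMR genes:          ", paste(object@mmrGenes, collapse = ", "), "\n")
  cat("  signature genes (", length(object@hypermutationGenes), "): ",
      paste(object@hypermutationGenes, collapse = ", "), "\n", sep = "")
  cat("  housekeeping genes: ", length(object@housekeepingGenes), "\n")
})

# -- ReferenceStats ----------------------------------------------------------

#' Accessors for ReferenceStats objects
#'
#' @param x a [ReferenceStats-class].
#' @return `mmrMu()`/`mmrSd()`: named numeric(4); `hyperWeights()`: named
#'   numeric(10); `hyperMuMss()`/`hyperSdMss()`: numeric(1).
#' @name ReferenceStats-accessors
NULL

#' @rdname ReferenceStats-accessors
#' @export
setMethod("mmrMu", "ReferenceStats", function(x) x@mmrMu)
#' @rdname ReferenceStats-accessors
#' @export
setMethod("mmrSd", "ReferenceStats", function(x) x@mmrSd)
#' @rdname ReferenceStats-accessors
#' @export
setMethod("hyperWeights", "ReferenceStats", function(x) x@hyperWeights)
#' @rdname ReferenceStats-accessors
#' @export
setMethod("hyperMuMss", "ReferenceStats", function(x) x@hyperMuMss)
#' @rdname ReferenceStats-accessors
#' @export
setMethod("hyperSdMss", "ReferenceStats", function(x) x@hyperSdMss)
#' @rdname ReferenceStats-accessors
#' @export
setMethod("housekeepingGenes", "ReferenceStats",
          function(x) x@housekeepingGenes)

setMethod("show", "ReferenceStats", function(object) {
  cat("ReferenceStats (MSS reference for MSI scoring)\n")
  cat("  MMR gene mu:", paste(sprintf("%s=%.3f", names(object@mmrMu),
                                      object@mmrMu), collapse = "  "), "\n")
  cat("  MMR gene sd:", paste(sprintf("%s=%.3f", names(object@mmrSd),
                                      object@mmrSd), collapse = "  "), "\n")
  cat(sprintf("  Hypermutation score MSS null: mu=%.4f sd=%.4f\n",
              object@hyperMuMss, object@hyperSdMss))
  cat("  signature genes:", paste(names(object@hyperWeights),
                                  collapse = ", "), "\n")
})

# -- MixtureFit --------------------------------------------------------------

#' Accessors for MixtureFit objects
#'
#' @param x a [MixtureFit-class].
#' @return `mixtureMeans()`: c(low, high); `mixtureSds()`: c(low, high);
#'   `mixtureWeights()`: c(low, high) mixing proportions; `bic()`:
#'   numeric(1).
#' @name MixtureFit-accessors
NULL

#' @rdname MixtureFit-accessors
#' @export
setMethod("mixtureMeans", "MixtureFit",
          function(x) c(low = x@muLow, high = x@muHigh))
#' @rdname MixtureFit-accessors
#' @export
setMethod("mixtureSds", "MixtureFit",
          function(x) c(low = x@sdLow, high = x@sdHigh))
#' @rdname MixtureFit-accessors
#' @export
setMethod("mixtureWeights", "MixtureFit",
          function(x) c(low = x@piLow, high = 1 - x@piLow))
#' @rdname MixtureFit-accessors
#' @export
setMethod("bic", "MixtureFit", function(x) x@bic)

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit (%s variance): pi=(%.3f, %.3f)  mu=(%.3f, %.3f)  sd=(%.3f, %.3f)\n",
    object@model, object@piLow, 1 - object@piLow,
    object@muLow, object@muHigh, object@sdLow, object@sdHigh))
  cat(sprintf("  logLik=%.3f  BIC=%.3f  converged=%s (%d iterations)\n",
              object@logLik, object@bic, object@converged, object@iterations))
})

# -- RocResult ---------------------------------------------------------------

#' Accessors for RocResult objects
#'
#' @param x a [RocResult-class].
#' @return `auc()`: numeric(1); `rocPoints()`: data.frame with columns
#'   threshold, tpr, fpr.
#' @name RocResult-accessors
NULL

#' @rdname RocResult-accessors
#' @export
setMethod("auc", "RocResult", function(x) x@auc)
#' @rdname RocResult-accessors
#' @export
setMethod("rocPoints", "RocResult", function(x)
  data.frame(threshold = x@thresholds, tpr = x@tpr, fpr = x@fpr))

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f (%d sweep points, direction = %s)\n",
              object@auc, length(object@thresholds), object@direction))
})
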