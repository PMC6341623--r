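#' @import methods
NULL

.MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

#' GenePanel: the gene sets consumed by the MSI scores
#'
#' Holds the three gene roles the classifier needs: the four mismatch-repair
#' (MMR) genes whose expression loss is scored, the ten hypermutation
#' signature genes of the weighted linear predictor, and a housekeeping set
#' used for per-sample normalization. The three sets must be pairwise
#' disjoint.
#'
#' @slot mmrGenes character(4), the MMR genes (MLH1, MSH2, MSH6, PMS2).
#' @slot hypermutationGenes character(10), the signature genes, in weight
#'   order.
#' @slot housekeepingGenes character, at least one housekeeping gene id.
#'
#' @seealso [defaultGenePanel()], [validatePanel()]
#' @export
setClass("GenePanel",
  representation(
    mmrGenes = "character",
    hypermutationGenes = "character",
    housekeepingGenes = "character"
  )
)

setValidity("GenePanel", function(object) {
  msg <- character()
  if (length(object@mmrGenes) != 4L)
    msg <- c(msg, "mmrGenes must contain exactly 4 gene ids")
  if (length(object@hypermutationGenes) != 10L)
    msg <- c(msg, "hypermutationGenes must contain exactly 10 gene ids")
  if (length(object@housekeepingGenes) < 1L)
    msg <- c(msg, "housekeepingGenes must contain at least one gene id")
  all_ids <- c(object@mmrGenes, object@hypermutationGenes,
               object@housekeepingGenes)
  if (anyDuplicated(all_ids))
    msg <- c(msg, sprintf(
      "gene roles must be pairwise disjoint; duplicated: %s",
      paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ReferenceStats: trained reference parameters for the MSI scores
#'
#' The full parameter set needed to score a cohort: per-MMR-gene mean and SD
#' of log2 expression in microsatellite-stable (MSS) tumors, the fixed
#' hypermutation signature weights, and the mean/SD of the Hypermutation
#' Predictor score in MSS tumors. SDs are trained as IQR / 1.349 for
#' robustness to the MSI-H tail.
#'
#' @slot mmrMu named numeric(4), MSS mean log2 expression per MMR gene.
#' @slot mmrSd named numeric(4), MSS SD per MMR gene, strictly positive.
#' @slot hyperWeights named numeric(10), signature gene weights.
#' @slot hyperMuMss numeric(1), MSS mean of the Hypermutation Predictor score.
#' @slot hyperSdMss numeric(1), MSS SD of the score, strictly positive.
#' @slot housekeepingGenes character, housekeeping set used at training time.
#'
#' @seealso [estimateReference()], [calibrateReference()], [scoreCohort()]
#' @export
setClass("ReferenceStats",
  representation(
    mmrMu = "numeric",
    mmrSd = "numeric",
    hyperWeights = "numeric",
    hyperMuMss = "numeric",
    hyperSdMss = "numeric",
    housekeepingGenes = "character"
  )
)

setValidity("ReferenceStats", function(object) {
  msg <- character()
  if (!setequal(names(object@mmrMu), .MMR_GENES) ||
      !setequal(names(object@mmrSd), .MMR_GENES))
    msg <- c(msg, "mmrMu and mmrSd must be named with the 4 MMR genes")
  if (length(object@hyperWeights) != 10L ||
      is.null(names(object@hyperWeights)) ||
      anyDuplicated(names(object@hyperWeights)))
    msg <- c(msg, "hyperWeights must be 10 uniquely named weights")
  if (any(!is.finite(object@mmrSd)) || any(object@mmrSd <= 0))
    msg <- c(msg, "all mmrSd values must be finite and > 0")
  if (length(object@hyperSdMss) != 1L || !is.finite(object@hyperSdMss) ||
      object@hyperSdMss <= 0)
    msg <- c(msg, "hyperSdMss must be a single finite value > 0")
  if (length(object@hyperMuMss) != 1L || !is.finite(object@hyperMuMss))
    msg <- c(msg, "hyperMuMss must be a single finite value")
  if (length(msg)) msg else TRUE
})

#' MixtureFit: a two-component 1-D Gaussian mixture fit
#'
#' Result of fitting a two-component Gaussian mixture by EM to one feature
#' (one MMR gene's log2 expression, or the Hypermutation Predictor score).
#' Components are canonically ordered so that `muLow < muHigh`.
#'
#' @slot muLow,muHigh numeric(1), component means, `muLow < muHigh`.
#' @slot sdLow,sdHigh numeric(1), component SDs, > 0 (equal under the
#'   equal-variance model).
#' @slot piLow numeric(1), mixing proportion of the low component, in (0,1).
#' @slot bic numeric(1), Bayesian information criterion of the fit.
#' @slot model "equal" or "unequal" component variances.
#' @slot logLik numeric(1), final log-likelihood.
#' @slot converged logical(1), whether EM met the relative tolerance.
#' @slot iterations integer(1), EM iterations used.
#' @slot responsibilities numeric, per-observation posterior probability of
#'   the low component.
#'
#' @seealso [fitMixture1d()], [calibrateReference()]
#' @export
setClass("MixtureFit",
  representation(
    muLow = "numeric", muHigh = "numeric",
    sdLow = "numeric", sdHigh = "numeric",
    piLow = "numeric", bic = "numeric",
    model = "character", logLik = "numeric",
    converged = "logical", iterations = "integer",
    responsibilities = "numeric"
  )
)

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (object@muLow > object@muHigh)
    msg <- c(msg, "muLow must be <= muHigh (ordering is canonicalized)")
  if (object@sdLow <= 0 || object@sdHigh <= 0)
    msg <- c(msg, "component SDs must be > 0")
  if (object@piLow <= 0 || object@piLow >= 1)
    msg <- c(msg, "piLow must be in (0, 1)")
  if (!object@model %in% c("equal", "unequal"))
    msg <- c(msg, "model must be 'equal' or 'unequal'")
  if (any(object@responsibilities < 0 | object@responsibilities > 1))
    msg <- c(msg, "responsibilities must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' RocResult: an ROC curve with its AUC
#'
#' @slot thresholds numeric, score cutoffs of the sweep (on the oriented
#'   scale where higher means positive).
#' @slot tpr,fpr numeric, true/false positive rates along the sweep,
#'   nondecreasing.
#' @slot auc numeric(1), area under the curve; equals both the trapezoidal
#'   area and the tie-aware pair-counting (Mann-Whitney) statistic.
#' @slot direction "higher" or "lower": whether larger or smaller raw scores
#'   indicate the positive class.
#'
#' @seealso [rocCurve()]
#' @export
setClass("RocResult",
  representation(
    thresholds = "numeric",
    tpr = "numeric",
    fpr = "numeric",
    auc = "numeric",
    direction = "character"
  )
)

setValidity("RocResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (is.unsorted(object@tpr) || is.unsorted(object@fpr))
    msg <- c(msg, "tpr and fpr must be nondecreasing along the sweep")
  if (!object@direction %in% c("higher", "lower"))
    msg <- c(msg, "direction must be 'higher' or 'lower'")
  if (length(msg)) msg else TRUE
})
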