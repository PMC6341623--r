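#' Published Hypermutation Predictor gene weights
#'
#' The fixed weights of the 10-gene linear predictor of tumor hypermutation
#' status, trained on TCGA colon, stomach and endometrial RNA-seq cohorts.
#' Negative-weight genes are under-expressed in hypermutated tumors
#' (EPM2AIP1 shares a bidirectional promoter with MLH1), positive-weight
#' genes over-expressed (DNA replication/metabolism, e.g. TYMS, WDR76).
#' The weights sum to ~0 and their absolute values to ~2, so the score is
#' invariant to uniform per-sample shifts and lives on a fixed contrast
#' scale.
#'
#' @return named numeric(10) of weights.
#' @examples
#' w <- hypermutationWeights()
#' sum(w)       # ~0: uniform shifts cancel
#' sum(abs(w))  # ~2
#' @export
hypermutationWeights <- function() {
  c(EPM2AIP1 = -0.31218,
    TTC30A   = -0.19894,
    SMAP1    = -0.1835,
    RNLS     = -0.19023,
    WNT11    = -0.11515,
    SFXN1    =  0.214676,
    SREBF1   =  0.194835,
    TYMS     =  0.206972,
    EIF5AL1  =  0.194935,
    WDR76    =  0.188582)
}
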