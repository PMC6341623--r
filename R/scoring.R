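#' @include AllClasses.R expression-io.R
NULL

#' MMR Loss score and p-value
#'
#' Standardizes each mismatch-repair gene's log2 expression against its MSS
#' reference, `z_g = (x_g - mu_g) / sd_g`, and reports the most severe loss:
#' the minimum z across MLH1, MSH2, MSH6 and PMS2. Only under-expression is
#' evidence of loss, so the p-value is the lower-tail probability of the
#' minimum of four independent standard normals (a Sidak-style correction):
#' `p = 1 - (1 - pnorm(score))^4`. At score 0 this is 1 - 0.5^4 = 0.9375.
#'
#' @param x named numeric with (at least) the four MMR genes, or a
#'   4 x samples matrix slice; a full genes x samples matrix also works.
#' @param ref a [ReferenceStats-class].
#' @return list with `z` (4 x n matrix of z-scores), `score` (per-sample min
#'   z) and `p` (per-sample p-value).
#' @export
mmrLoss <- function(x, ref) {
  if (is.null(dim(x))) x <- cbind(sample = x)
  mmr <- names(mmrMu(ref))
  missing <- setdiff(mmr, rownames(x))
  if (length(missing))
    stop("MMR gene(s) absent: ", paste(missing, collapse = ", "))
  xm <- x[mmr, , drop = FALSE]
  if (any(!is.finite(xm))) stop("non-finite MMR gene expression values")
  z <- (xm - mmrMu(ref)[mmr]) / mmrSd(ref)[mmr]
  score <- apply(z, 2L, min)
  p <- 1 - (1 - stats::pnorm(score))^4
  list(z = z, score = score, p = p)
}

# Raw weighted sum over the signature genes; no centering.
hypermutationScoreRaw <- function(x, weights) {
  if (is.null(dim(x))) x <- cbind(sample = x)
  missing <- setdiff(names(weights), rownames(x))
  if (length(missing))
    stop("signature gene(s) absent: ", paste(missing, collapse = ", "))
  colSums(x[names(weights), , drop = FALSE] * weights)
}

#' Hypermutation Predictor score and p-value
#'
#' The weighted linear predictor `score = sum_g w_g x_g` over the ten
#' signature genes, referred to its MSS null: the p-value is the upper-tail
#' normal probability `1 - pnorm((score - mu_MSS) / sd_MSS)` (high scores
#' indicate hypermutation).
#'
#' @param x named numeric or genes x samples matrix of log2 expression.
#' @param ref a [ReferenceStats-class] (supplies the weights and MSS null).
#' @return list with `score` and `p`, one entry per sample.
#' @export
hypermutationScore <- function(x, ref) {
  score <- hypermutationScoreRaw(x, hyperWeights(ref))
  z <- (score - hyperMuMss(ref)) / hyperSdMss(ref)
  list(score = score, p = 1 - stats::pnorm(z))
}

#' Combine the two scores into the MSI Predictor p-value
#'
#' Combines the MMR Loss and Hypermutation Predictor p-values so that (a)
#' strong evidence from either score cannot be counteracted by the other,
#' and (b) moderate evidence from both accumulates. Both inputs are
#' truncated at the neutral-evidence point 0.5 before Fisher combination
#' (chi-squared with 4 df), and the result is floored by the truncated
#' individual p-values:
#' `p_msi = min(p*_mmr, p*_hyper, pchisq(-2 (log p*_mmr + log p*_hyper), 4,
#' lower = FALSE))` with `p* = min(p, 0.5)`. The truncation means a p-value
#' above 0.5 (no evidence) enters as exactly neutral rather than as
#' evidence against, so `combineMsi(1, 1)` equals `combineMsi(0.5, 0.5)`.
#'
#' @param pMmr,pHyper numeric vectors of p-values in (0, 1]; values <= 0 are
#'   clamped to the smallest positive double with a warning.
#' @return numeric vector of combined MSI Predictor p-values;
#'   always `<= min(pMmr, pHyper)` elementwise, and symmetric in its
#'   arguments.
#' @export
combineMsi <- function(pMmr, pHyper) {
  if (length(pMmr) != length(pHyper))
    stop("pMmr and pHyper must have equal length")
  if (any(pMmr > 1 | pHyper > 1, na.rm = TRUE))
    stop("p-values must be <= 1")
  clamp <- function(p) {
    if (any(p <= 0)) {
      warning("p-value(s) <= 0 clamped to the smallest positive double")
      p[p <= 0] <- .Machine$double.xmin
    }
    p
  }
  pMmr <- pmin(clamp(pMmr), 0.5)
  pHyper <- pmin(clamp(pHyper), 0.5)
  x <- -2 * (log(pMmr) + log(pHyper))
  pFisher <- stats::pchisq(x, df = 4, lower.tail = FALSE)
  unname(pmin(pMmr, pHyper, pFisher))
}

#' Score a cohort for MSI
#'
#' Computes, per sample, the MMR z-scores, MMR Loss score and p-value, the
#' Hypermutation Predictor score and p-value, the combined MSI Predictor
#' p-value, and the MSS / MSI-H call at the given p-value threshold.
#'
#' @param m genes x samples log2 matrix or SummarizedExperiment; must
#'   contain all 14 scoring genes. Normalize first with
#'   [normalizeHousekeeping()].
#' @param ref a [ReferenceStats-class].
#' @param threshold call threshold on the MSI Predictor p-value
#'   (default 0.01).
#' @param panel optional [GenePanel-class] for coverage validation; defaults
#'   to the genes named in `ref`.
#' @return a [S4Vectors::DataFrame] with one row per sample and columns
#'   `sample_id`, `z_MLH1`, `z_MSH2`, `z_MSH6`, `z_PMS2`, `mmr_loss_score`,
#'   `p_mmr`, `hyper_score`, `p_hyper`, `p_msi`, `call`; the threshold is
#'   recorded in its metadata.
#' @examples
#' cohort <- generateCohort(syntheticConfig(nSamples = 60, seed = 7))
#' ref <- estimateReference(cohort, SummarizedExperiment::colData(cohort)$status)
#' head(scoreCohort(cohort, ref))
#' @export
scoreCohort <- function(m, ref, threshold = 0.01, panel = NULL) {
  m <- .asExprMatrix(m)
  if (is.null(panel))
    panel <- GenePanel(names(mmrMu(ref)), names(hyperWeights(ref)),
                       housekeepingGenes(ref))
  .stopOnPanelFailure(m, panel)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")

  ml <- tryCatch(mmrLoss(m, ref), error = function(e)
    stop("MMR Loss scoring failed: ", conditionMessage(e)))
  hs <- tryCatch(hypermutationScore(m, ref), error = function(e)
    stop("Hypermutation scoring failed: ", conditionMessage(e)))
  p_msi <- combineMsi(unname(ml$p), unname(hs$p))

  out <- S4Vectors::DataFrame(
    sample_id = colnames(m),
    t(ml$z)[, names(mmrMu(ref)), drop = FALSE],
    mmr_loss_score = unname(ml$score),
    p_mmr = unname(ml$p),
    hyper_score = unname(hs$score),
    p_hyper = unname(hs$p),
    p_msi = unname(p_msi),
    call = ifelse(p_msi < threshold, "MSI-H", "MSS"),
    row.names = colnames(m))
  colnames(out)[2:5] <- paste0("z_", names(mmrMu(ref)))
  S4Vectors::metadata(out)$threshold <- threshold
  out
}
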