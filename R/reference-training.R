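#' @include AllClasses.R expression-io.R weights.R
NULL

# Robust SD from the interquartile range under normality:
# IQR of N(0,1) = 2 * qnorm(0.75) = 1.349.
.IQR_TO_SD <- 2 * stats::qnorm(0.75)

.checkLabels <- function(labels, sample_ids) {
  labels <- as.character(labels)
  if (length(labels) != length(sample_ids))
    stop("labels must have one entry per sample (",
         length(sample_ids), " samples, ", length(labels), " labels)")
  bad <- setdiff(unique(labels), c("MSS", "MSI-H"))
  if (length(bad))
    stop("labels must be 'MSS' or 'MSI-H'; found: ",
         paste(bad, collapse = ", "))
  labels
}

#' Estimate MSS reference statistics from a labeled cohort
#'
#' Trains the reference parameters the scores need, using only the
#' microsatellite-stable (MSS) samples: per-MMR-gene mean log2 expression and
#' robust SD (IQR / 1.349), and the mean and robust SD of the Hypermutation
#' Predictor score. The IQR-based SD keeps the reference insensitive to any
#' mislabeled or borderline low-expression samples in the training set.
#'
#' @param m genes x samples log2 matrix (or SummarizedExperiment), already
#'   housekeeping-normalized.
#' @param labels per-sample `"MSS"` / `"MSI-H"` labels, aligned to columns
#'   of `m`; at least 8 MSS samples are required.
#' @param weights named numeric(10) signature weights
#'   (default [hypermutationWeights()]).
#' @param panel a [GenePanel-class] naming the genes.
#' @return a [ReferenceStats-class].
#' @export
estimateReference <- function(m, labels, weights = hypermutationWeights(),
                              panel = defaultGenePanel()) {
  m <- .asExprMatrix(m)
  labels <- .checkLabels(labels, colnames(m))
  missing <- setdiff(scoringGenes(panel), rownames(m))
  if (length(missing))
    stop("scoring gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  mss <- which(labels == "MSS")
  if (length(mss) < 8L)
    stop("need at least 8 MSS samples to train, found ", length(mss))

  robust_sd <- function(v, what) {
    iqr <- stats::IQR(v)
    if (iqr <= 0)
      stop("degenerate (zero-IQR) distribution for ", what,
           " in MSS samples")
    iqr / .IQR_TO_SD
  }

  mmr <- mmrGenes(panel)
  mmr_x <- m[mmr, mss, drop = FALSE]
  mmr_mu <- rowMeans(mmr_x)
  mmr_sd <- vapply(mmr, function(g) robust_sd(mmr_x[g, ], g), numeric(1))

  hs <- hypermutationScoreRaw(m[, mss, drop = FALSE], weights)
  new("ReferenceStats",
      mmrMu = mmr_mu, mmrSd = mmr_sd,
      hyperWeights = weights,
      hyperMuMss = mean(hs),
      hyperSdMss = robust_sd(hs, "the Hypermutation Predictor score"),
      housekeepingGenes = housekeepingGenes(panel))
}

#' Genome-wide two-group differential expression screen
#'
#' Fits, per gene, the univariate linear model of log2 expression on binary
#' hypermutation status (equivalent to a two-sample t-test with pooled
#' variance) and applies Benjamini-Hochberg FDR adjustment over all tested
#' genes. The linear models are fit with `limma::lmFit`; the returned t and p
#' are the ordinary (unmoderated) statistics.
#'
#' @param m genes x samples log2 matrix (or SummarizedExperiment).
#' @param labels binary per-sample status; coerced so that the effect is the
#'   mean difference (group 1 minus group 0) in log2 units. `"MSI-H"`/`"MSS"`
#'   labels are mapped to 1/0.
#' @return data.frame with columns `gene`, `effect`, `t`, `p_value`, `fdr`,
#'   sorted by `p_value`. Constant genes get `p_value = 1`.
#' @export
deScreen <- function(m, labels) {
  m <- .asExprMatrix(m)
  grp <- labels
  if (is.character(grp) || is.factor(grp)) {
    grp <- as.character(grp)
    if (all(grp %in% c("MSS", "MSI-H"))) grp <- as.integer(grp == "MSI-H")
    else stop("character labels must be 'MSS'/'MSI-H'")
  }
  grp <- as.integer(grp)
  if (!all(grp %in% 0:1)) stop("labels must be binary (0/1 or MSS/MSI-H)")
  if (length(grp) != ncol(m)) stop("labels must match the number of samples")
  if (min(table(factor(grp, levels = 0:1))) < 2L)
    stop("both groups need at least 2 samples")

  design <- stats::model.matrix(~grp)
  fit <- limma::lmFit(m, design)
  effect <- fit$coefficients[, "grp"]
  se <- fit$stdev.unscaled[, "grp"] * fit$sigma
  t <- effect / se
  p <- 2 * stats::pt(-abs(t), df = fit$df.residual)
  rng <- apply(m, 1L, function(r) max(r) - min(r))
  degenerate <- !is.finite(p) | rng == 0   # constant genes carry no signal
  p[degenerate] <- 1
  t[degenerate] <- 0
  effect[degenerate] <- 0
  res <- data.frame(gene = rownames(m), effect = effect, t = t,
                    p_value = p, fdr = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  res[order(res$p_value), , drop = FALSE]
}

#' Select a cross-cohort consistent signature
#'
#' Given differential-expression screens from two or more cohorts, keeps the
#' genes that are significant (FDR < `fdrCutoff`) with a consistent effect
#' sign in every cohort, ranks them by worst-case absolute effect (the
#' smallest |effect| across cohorts), and truncates to `k`.
#'
#' @param deByDataset list of >= 2 data.frames as returned by [deScreen()].
#' @param k number of genes to return.
#' @param fdrCutoff per-cohort FDR significance cutoff (default 0.05).
#' @param exclude optional character vector of gene ids to drop before
#'   selection (e.g. to mirror screens refit on sample subsets).
#' @return character vector of up to `k` gene ids, strongest first; a
#'   warning is raised if fewer than `k` qualify.
#' @export
selectSignature <- function(deByDataset, k, fdrCutoff = 0.05,
                            exclude = NULL) {
  if (length(deByDataset) < 2L)
    stop("need at least 2 differential-expression screens")
  shared <- Reduce(intersect, lapply(deByDataset, function(d) d$gene))
  shared <- setdiff(shared, exclude)
  if (!length(shared)) stop("the gene universes do not overlap")

  eff <- sapply(deByDataset, function(d)
    d$effect[match(shared, d$gene)])
  fdr <- sapply(deByDataset, function(d)
    d$fdr[match(shared, d$gene)])
  if (is.null(dim(eff))) { eff <- rbind(eff); fdr <- rbind(fdr) }

  signif_all <- apply(fdr < fdrCutoff, 1L, all)
  sign_consistent <- apply(sign(eff), 1L, function(s)
    all(s == s[1L]) && s[1L] != 0)
  ok <- shared[signif_all & sign_consistent]
  if (!length(ok)) {
    warning("no genes are significant with a consistent sign in all cohorts")
    return(character())
  }
  worst <- apply(abs(eff[match(ok, shared), , drop = FALSE]), 1L, min)
  ok <- ok[order(worst, decreasing = TRUE)]
  if (length(ok) < k)
    warning(sprintf("only %d gene(s) qualify (requested %d)",
                    length(ok), k))
  utils::head(ok, k)
}
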