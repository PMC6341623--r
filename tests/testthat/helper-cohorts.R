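# Shared fixtures, all built in code.

hkGenes <- function(n = 10) sprintf("HK%02d", seq_len(n))

# Panel-complete matrix where every gene sits exactly at `mu` unless
# overridden; useful for analytic scoring checks.
flatPanelMatrix <- function(nSamples = 1, mu = 10) {
  genes <- c(mmrGenes(defaultGenePanel()), names(hypermutationWeights()),
             hkGenes())
  matrix(mu, nrow = length(genes), ncol = nSamples,
         dimnames = list(genes, sprintf("S%03d", seq_len(nSamples))))
}

# An exact reference (no estimation noise) matching flatPanelMatrix().
exactReference <- function(mu = 10, sd = 1, hyperMu = NULL, hyperSd = NULL) {
  w <- hypermutationWeights()
  if (is.null(hyperMu)) hyperMu <- sum(w) * mu
  if (is.null(hyperSd)) hyperSd <- sqrt(sum(w^2)) * sd
  new("ReferenceStats",
      mmrMu = setNames(rep(mu, 4), mmrGenes(defaultGenePanel())),
      mmrSd = setNames(rep(sd, 4), mmrGenes(defaultGenePanel())),
      hyperWeights = w, hyperMuMss = hyperMu, hyperSdMss = hyperSd,
      housekeepingGenes = hkGenes())
}

# Normalized matrix + truth labels from a generated cohort.
normalizedCohort <- function(cfg) {
  se <- generateCohort(cfg)
  list(m = normalizeHousekeeping(SummarizedExperiment::assay(se), hkGenes()),
       truth = SummarizedExperiment::colData(se)$status,
       mechanism = SummarizedExperiment::colData(se)$mechanism)
}

# Brute-force trapezoidal area under an ROC point set (test oracle).
trapezoidArea <- function(fpr, tpr) {
  o <- order(fpr, tpr)
  sum(diff(fpr[o]) * (utils::head(tpr[o], -1) + utils::tail(tpr[o], -1)) / 2)
}
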