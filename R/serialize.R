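#' @include AllClasses.R
NULL

#' Write / read ReferenceStats as YAML
#'
#' The YAML layout carries the full parameter set plus an optional
#' provenance block (sample counts, seed, package version, timestamp) so
#' scoring runs are re-derivable.
#'
#' @param ref a [ReferenceStats-class].
#' @param path output / input YAML path.
#' @param provenance optional named list echoed into a `provenance` block.
#' @return `referenceToYaml`: `path`, invisibly. `referenceFromYaml`: a
#'   [ReferenceStats-class].
#' @export
referenceToYaml <- function(ref, path, provenance = NULL) {
  obj <- list(
    mmr_mu = as.list(mmrMu(ref)),
    mmr_sd = as.list(mmrSd(ref)),
    hyper_weights = as.list(hyperWeights(ref)),
    hyper_mu_mss = hyperMuMss(ref),
    hyper_sd_mss = hyperSdMss(ref),
    housekeeping_genes = as.list(housekeepingGenes(ref)))
  if (!is.null(provenance)) obj$provenance <- provenance
  yaml::write_yaml(obj, path, precision = 17L)
  invisible(path)
}

#' @rdname referenceToYaml
#' @export
referenceFromYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  need <- c("mmr_mu", "mmr_sd", "hyper_weights", "hyper_mu_mss",
            "hyper_sd_mss", "housekeeping_genes")
  missing <- setdiff(need, names(obj))
  if (length(missing))
    stop("reference YAML is missing field(s): ",
         paste(missing, collapse = ", "))
  new("ReferenceStats",
      mmrMu = unlist(obj$mmr_mu),
      mmrSd = unlist(obj$mmr_sd),
      hyperWeights = unlist(obj$hyper_weights),
      hyperMuMss = as.numeric(obj$hyper_mu_mss),
      hyperSdMss = as.numeric(obj$hyper_sd_mss),
      housekeepingGenes = as.character(unlist(obj$housekeeping_genes)))
}

#' Score a stored validation cohort end to end
#'
#' One-call pipeline for an external validation set: read the expression
#' matrix and truth labels, housekeeping-normalize, calibrate the trained
#' reference to the new platform (unsupervised; labels are never consulted
#' before evaluation), score, and evaluate.
#'
#' @param matrixPath CSV/TSV of log2 expression, genes in rows.
#' @param labelsPath CSV with columns `sample_id` and `status`
#'   (`MSS`/`MSI-H`).
#' @param ref trained [ReferenceStats-class] (e.g. from
#'   [referenceFromYaml()]).
#' @param threshold call threshold on the MSI Predictor p-value.
#' @param calibrate whether to run platform calibration before scoring
#'   (default TRUE).
#' @return list with `scores` (per-sample table), `auc` (named AUCs of the
#'   three algorithms), `table` (TPR/FPR with Wilson CIs) and
#'   `sens_full_spec` (sensitivity at 100% specificity of the MSI
#'   Predictor).
#' @export
validationBenchmark <- function(matrixPath, labelsPath, ref,
                                threshold = 0.01, calibrate = TRUE) {
  m <- readExpressionMatrix(matrixPath)
  lab <- utils::read.csv(labelsPath, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% colnames(lab)))
    stop("labels file needs columns sample_id and status")
  missing <- setdiff(colnames(m), lab$sample_id)
  if (length(missing))
    stop("labels missing for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  truth <- stats::setNames(lab$status, lab$sample_id)[colnames(m)]

  hk <- intersect(housekeepingGenes(ref), rownames(m))
  if (length(hk)) m <- normalizeHousekeeping(m, hk)
  if (isTRUE(calibrate)) ref <- calibrateReference(m, ref)$reference
  scores <- scoreCohort(m, ref, threshold = threshold)

  list(scores = scores,
       auc = c(mmr_loss = auc(rocCurve(scores$p_mmr, truth)),
               hypermutation = auc(rocCurve(scores$p_hyper, truth)),
               msi_predictor = auc(rocCurve(scores$p_msi, truth))),
       table = tprFprTable(scores, truth, threshold = threshold),
       sens_full_spec =
         sensitivityAtFullSpecificity(scores$p_msi, truth)$sensitivity)
}
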