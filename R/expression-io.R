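#' @include AllClasses.R
NULL

#' Construct a gene panel
#'
#' @param mmrGenes character(4): the mismatch-repair genes to score for
#'   expression loss.
#' @param hypermutationGenes character(10): the signature genes of the
#'   Hypermutation Predictor, in weight order.
#' @param housekeepingGenes character: housekeeping genes used for per-sample
#'   normalization.
#' @return a [GenePanel-class].
#' @examples
#' GenePanel(c("MLH1", "MSH2", "MSH6", "PMS2"),
#'           names(hypermutationWeights()),
#'           paste0("HK", 1:10))
#' @export
GenePanel <- function(mmrGenes, hypermutationGenes, housekeepingGenes) {
  new("GenePanel",
      mmrGenes = as.character(mmrGenes),
      hypermutationGenes = as.character(hypermutationGenes),
      housekeepingGenes = as.character(housekeepingGenes))
}

#' The default gene panel
#'
#' MMR genes MLH1, MSH2, MSH6, PMS2; the ten published signature genes; and a
#' configurable housekeeping set. The identities of the housekeeping genes
#' are platform-specific and must ultimately come from the assay's panel
#' configuration; the default names (`HK01`..`HK10`) match the synthetic
#' cohort generator.
#'
#' @param housekeeping character vector of housekeeping gene ids.
#' @return a [GenePanel-class].
#' @export
defaultGenePanel <- function(housekeeping = sprintf("HK%02d", 1:10)) {
  GenePanel(.MMR_GENES, names(hypermutationWeights()), housekeeping)
}

#' Read a gene panel from a YAML config
#'
#' The file must define `mmr_genes`, `hypermutation_genes` and
#' `housekeeping_genes` as lists of gene ids.
#'
#' @param path YAML file path.
#' @return a [GenePanel-class].
#' @export
genePanelFromYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("mmr_genes", "hypermutation_genes", "housekeeping_genes")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("panel config is missing field(s): ", paste(missing, collapse = ", "))
  GenePanel(unlist(cfg$mmr_genes), unlist(cfg$hypermutation_genes),
            unlist(cfg$housekeeping_genes))
}

# Accept a plain matrix or a SummarizedExperiment (first assay); always
# return a genes x samples numeric matrix with dimnames.
.asExprMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix or SummarizedExperiment")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values; ",
         "missing entries are rejected, not imputed")
  x
}

#' Read an expression matrix from delimited text
#'
#' Reads a CSV/TSV file with one header row and one id column into a
#' genes-by-samples log2 expression matrix. Values are expected on the log2
#' scale already; supply `log2Offset` to apply `log2(x + offset)` to raw
#' linear-scale values.
#'
#' @param path file path. The delimiter is inferred from the extension
#'   (`.csv` comma, otherwise tab) unless `sep` is given.
#' @param orientation `"genes-in-rows"` (default) or `"samples-in-rows"`;
#'   the returned matrix is always genes x samples.
#' @param sep field delimiter override.
#' @param log2Offset if non-`NULL`, values are linear-scale and
#'   `log2(x + log2Offset)` is applied (offset default used by callers: 1).
#' @return numeric matrix, genes x samples, ids preserved verbatim.
#' @export
readExpressionMatrix <- function(path,
                                 orientation = c("genes-in-rows",
                                                 "samples-in-rows"),
                                 sep = NULL, log2Offset = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "\"", fill = FALSE)
  if (ncol(df) < 2L)
    stop("expected an id column plus at least one data column in ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  num <- df[, -1L, drop = FALSE]
  bad <- !vapply(num, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric cells in column(s): ",
         paste(colnames(num)[bad], collapse = ", "))
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples-in-rows") m <- t(m)
  if (!is.null(log2Offset)) {
    if (any(m + log2Offset <= 0))
      stop("log2 transform undefined: values <= -log2Offset present")
    m <- log2(m + log2Offset)
  }
  .asExprMatrix(m)
}

#' Write an expression matrix as CSV
#'
#' @param m genes x samples matrix.
#' @param path output CSV path (genes in rows, id column `gene_id`).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(m, path) {
  m <- .asExprMatrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Housekeeping normalization
#'
#' Shifts each sample by a single additive constant so that its mean log2
#' expression over the housekeeping genes equals `target`. With the default
#' grand-mean target the normalization is dataset-internal: the target is the
#' mean over samples of the per-sample housekeeping means of the input. The
#' operation is idempotent and preserves all within-sample differences
#' between genes exactly.
#'
#' @param m genes x samples log2 matrix (or SummarizedExperiment).
#' @param hk character vector of housekeeping gene ids, all present in `m`.
#' @param target numeric(1) target housekeeping mean, or `"grand-mean"`.
#' @return the normalized matrix, same shape and dimnames as `m`.
#' @export
normalizeHousekeeping <- function(m, hk, target = "grand-mean") {
  m <- .asExprMatrix(m)
  missing <- setdiff(hk, rownames(m))
  if (length(missing))
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  hk_means <- colMeans(m[hk, , drop = FALSE])
  if (identical(target, "grand-mean")) target <- mean(hk_means)
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target))
    stop("target must be a single finite number or \"grand-mean\"")
  sweep(m, 2L, hk_means - target, "-")
}

#' Check a matrix's coverage of a gene panel
#'
#' Reports, per role, which panel genes are present and missing. Absence of
#' any of the 14 scoring genes (4 MMR + 10 signature) is a hard failure;
#' missing housekeeping genes only warrant a warning since the housekeeping
#' set is substitutable.
#'
#' @param m genes x samples matrix (or SummarizedExperiment).
#' @param panel a [GenePanel-class].
#' @return a list with one entry per role (`mmr`, `hypermutation`,
#'   `housekeeping`), each holding `present` and `missing` id vectors, plus
#'   `failed` (logical: any scoring gene absent) and `messages`.
#' @export
validatePanel <- function(m, panel) {
  m <- .asExprMatrix(m)
  roles <- list(mmr = mmrGenes(panel),
                hypermutation = hypermutationGenes(panel),
                housekeeping = housekeepingGenes(panel))
  report <- lapply(roles, function(g)
    list(present = intersect(g, rownames(m)),
         missing = setdiff(g, rownames(m))))
  hard <- c(report$mmr$missing, report$hypermutation$missing)
  msgs <- character()
  if (length(hard))
    msgs <- c(msgs, sprintf(
      "scoring gene(s) absent: %s (roles: %s)",
      paste(hard, collapse = ", "),
      paste(rep(c("mmr", "hypermutation"),
                c(length(report$mmr$missing),
                  length(report$hypermutation$missing))), collapse = ", ")))
  if (length(report$housekeeping$missing))
    msgs <- c(msgs, sprintf("housekeeping gene(s) absent (warning only): %s",
                            paste(report$housekeeping$missing,
                                  collapse = ", ")))
  c(report, list(failed = length(hard) > 0L, messages = msgs))
}

.stopOnPanelFailure <- function(m, panel) {
  rep <- validatePanel(m, panel)
  if (rep$failed) stop(rep$messages[[1L]])
  if (length(rep$housekeeping$missing))
    warning(rep$messages[[length(rep$messages)]])
  invisible(rep)
}
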