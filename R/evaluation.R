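#' @include AllClasses.R
NULL

.checkBinaryTruth <- function(truth, n) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth)
    if (!all(truth %in% c("MSS", "MSI-H")))
      stop("character truth must be 'MSS'/'MSI-H'")
    truth <- as.integer(truth == "MSI-H")
  }
  truth <- as.integer(truth)
  if (length(truth) != n) stop("truth must match the number of scores")
  if (!all(truth %in% 0:1)) stop("truth must be binary")
  if (length(unique(truth)) < 2L)
    stop("both classes must be present in truth")
  truth
}

#' ROC curve and AUC
#'
#' Sweeps all observed score cutoffs and returns the ROC curve plus the AUC.
#' The AUC is computed by tie-aware pair counting (the Mann-Whitney
#' statistic: ties count 0.5); the trapezoidal area under the returned curve
#' equals it exactly, which the class validity relies on. `direction =
#' "lower"` (the default, suited to p-value-like scores) treats smaller
#' scores as evidence for the positive class.
#'
#' @param scores numeric vector.
#' @param truth binary vector (1 / `"MSI-H"` = positive), both classes
#'   present.
#' @param direction `"lower"` or `"higher"`: which end of the score scale
#'   indicates the positive class.
#' @return a [RocResult-class].
#' @examples
#' auc(rocCurve(c(0.001, 0.2, 0.9, 0.04), c(1, 0, 0, 1)))
#' @export
rocCurve <- function(scores, truth, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  if (any(is.na(scores))) stop("scores must not contain NA")
  truth <- .checkBinaryTruth(truth, length(scores))
  s <- if (direction == "lower") -scores else scores

  # pair-counting AUC via midranks
  r <- rank(s, ties.method = "average")
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  auc <- (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # sweep: call positive iff oriented score >= threshold
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- cumsum(tapply(truth, factor(s, levels = sort(unique(s),
                                                      decreasing = TRUE)),
                       sum)) / n1
  fpr <- cumsum(tapply(1 - truth, factor(s, levels = sort(unique(s),
                                                          decreasing = TRUE)),
                       sum)) / n0
  new("RocResult",
      thresholds = c(Inf, thr),
      tpr = c(0, unname(tpr)),
      fpr = c(0, unname(fpr)),
      auc = auc, direction = direction)
}

#' Wilson score confidence interval for a proportion
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param conf confidence level (default 0.95).
#' @return data.frame with columns `rate`, `lo`, `hi`, `k`, `n`.
#' @examples
#' wilsonCi(0, 10)   # hi ~ 0.278
#' @export
wilsonCi <- function(k, n, conf = 0.95) {
  if (length(k) != length(n)) stop("k and n must have equal length")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(rate = p, lo = pmax(0, centre - half),
             hi = pmin(1, centre + half), k = k, n = n)
}

#' Sensitivity at 100% specificity
#'
#' Finds the largest p-value cutoff that makes no false-positive call
#' (strictly below the smallest negative-class p-value, with the call rule
#' `p < threshold`) and reports the fraction of positives detected at that
#' cutoff.
#'
#' @param scores p-value-like scores (lower = more positive).
#' @param truth binary vector (1 / `"MSI-H"` = positive).
#' @return list with `threshold` (the reported cutoff: the minimum
#'   negative-class score, used with a strict `<` call) and `sensitivity`.
#' @export
sensitivityAtFullSpecificity <- function(scores, truth) {
  scores <- as.numeric(scores)
  truth <- .checkBinaryTruth(truth, length(scores))
  thr <- min(scores[truth == 0L])
  list(threshold = thr,
       sensitivity = mean(scores[truth == 1L] < thr))
}

#' TPR/FPR table with Wilson confidence intervals
#'
#' Calls each of the three algorithms (MMR Loss, Hypermutation Predictor,
#' MSI Predictor) positive when its p-value is below `threshold`, then
#' tabulates the true positive rate over MSI-H samples and the false
#' positive rate over MSS samples with Wilson 95% intervals.
#'
#' @param records per-sample scores as returned by [scoreCohort()] (needs
#'   columns `sample_id`, `p_mmr`, `p_hyper`, `p_msi`).
#' @param truth named binary vector or `"MSS"`/`"MSI-H"` character vector;
#'   if named, it is aligned to `records$sample_id`.
#' @param threshold p-value call threshold (default 0.01).
#' @param conf confidence level for the Wilson intervals.
#' @return data.frame with one row per algorithm (`mmr_loss`,
#'   `hypermutation`, `msi_predictor`) and columns `tpr`, `tpr_lo`,
#'   `tpr_hi`, `fpr`, `fpr_lo`, `fpr_hi`, `n_pos`, `n_neg`.
#' @export
tprFprTable <- function(records, truth, threshold = 0.01, conf = 0.95) {
  records <- as.data.frame(records)
  need <- c("sample_id", "p_mmr", "p_hyper", "p_msi")
  if (!all(need %in% colnames(records)))
    stop("records must contain columns: ", paste(need, collapse = ", "))
  if (!is.null(names(truth))) {
    missing <- setdiff(records$sample_id, names(truth))
    if (length(missing))
      stop("truth is missing sample id(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    truth <- truth[records$sample_id]
  }
  truth <- .checkBinaryTruth(truth, nrow(records))

  algs <- c(mmr_loss = "p_mmr", hypermutation = "p_hyper",
            msi_predictor = "p_msi")
  pos <- truth == 1L
  rows <- lapply(names(algs), function(a) {
    called <- records[[algs[[a]]]] < threshold
    tp <- wilsonCi(sum(called & pos), sum(pos), conf)
    fp <- wilsonCi(sum(called & !pos), sum(!pos), conf)
    data.frame(algorithm = a,
               tpr = tp$rate, tpr_lo = tp$lo, tpr_hi = tp$hi,
               fpr = fp$rate, fpr_lo = fp$lo, fpr_hi = fp$hi,
               n_pos = sum(pos), n_neg = sum(!pos))
  })
  do.call(rbind, rows)
}
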