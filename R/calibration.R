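#' @include AllClasses.R scoring.R
NULL

.dnormSafe <- function(x, mu, sd) stats::dnorm(x, mu, sd)

#' Fit a two-component 1-D Gaussian mixture
#'
#' EM fit of a two-component Gaussian mixture to a numeric vector, with
#' deterministic initialization (the lower and upper halves of the sorted
#' data seed the two components), so repeated runs give identical results
#' without a seed. `model = "auto"` fits both the equal-variance and
#' unequal-variance models and keeps the one with lower BIC. Components are
#' relabeled post-fit so `muLow < muHigh`.
#'
#' Convergence: relative log-likelihood change < 1e-8, at most 500
#' iterations. Component SDs are floored at 1e-3 times the data SD to block
#' degenerate spikes.
#'
#' @param values numeric vector, >= 10 finite observations with nonzero
#'   variance.
#' @param model `"auto"` (default), `"equal"` or `"unequal"`.
#' @return a [MixtureFit-class]. Non-convergence is reported via
#'   `converged = FALSE` (with a warning), not an error.
#' @examples
#' fitMixture1d(c(rnorm(100, 0), rnorm(100, 5)))
#' @export
fitMixture1d <- function(values, model = c("auto", "equal", "unequal")) {
  model <- match.arg(model)
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  n <- length(x)
  if (n < 10L) stop("need at least 10 observations, got ", n)
  if (stats::sd(x) == 0) stop("values have zero variance")

  if (model == "auto") {
    fits <- list(.emFit(x, equal = TRUE), .emFit(x, equal = FALSE))
    # a component carrying < 3 expected observations is an outlier spike,
    # not a population cluster; prefer non-degenerate fits
    degen <- vapply(fits, function(f)
      min(f@piLow, 1 - f@piLow) * n < 3, logical(1))
    if (any(!degen)) fits <- fits[!degen]
    fit <- fits[[which.min(vapply(fits, function(f) f@bic, numeric(1)))]]
  } else {
    fit <- .emFit(x, equal = model == "equal")
    if (min(fit@piLow, 1 - fit@piLow) * n < 3)
      warning("smaller mixture component carries fewer than 3 expected ",
              "observations; fit may be degenerate")
  }
  if (!fit@converged)
    warning("EM did not converge within 500 iterations; ",
            "returning last parameters")
  fit
}

.emFit <- function(x, equal) {
  n <- length(x)
  xs <- sort(x)
  lower <- xs[seq_len(floor(n / 2))]
  upper <- xs[seq.int(floor(n / 2) + 1L, n)]
  sd_floor <- 1e-3 * stats::sd(x)
  guard <- function(s) max(s, sd_floor)

  mu <- c(mean(lower), mean(upper))
  if (equal) {
    s0 <- guard(sqrt(((length(lower) - 1) * stats::var(lower) +
                      (length(upper) - 1) * stats::var(upper)) / (n - 2)))
    sd <- c(s0, s0)
  } else {
    sd <- c(guard(stats::sd(lower)), guard(stats::sd(upper)))
  }
  pi1 <- 0.5
  ll <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d1 <- pi1 * .dnormSafe(x, mu[1], sd[1])
    d2 <- (1 - pi1) * .dnormSafe(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot                      # responsibility of component 1
    ll_new <- sum(log(tot))

    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break  # one component emptied out
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    if (equal) {
      s <- guard(sqrt((sum(g * (x - mu[1])^2) +
                       sum((1 - g) * (x - mu[2])^2)) / n))
      sd <- c(s, s)
    } else {
      sd <- c(guard(sqrt(sum(g * (x - mu[1])^2) / n1)),
              guard(sqrt(sum((1 - g) * (x - mu[2])^2) / n2)))
    }
    pi1 <- n1 / n

    if (is.finite(ll) && abs(ll_new - ll) < 1e-8 * abs(ll)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
    if (iter >= 500L) break
  }

  k <- if (equal) 4 else 5             # (mu1, mu2, sd[, sd2], pi)
  bic <- -2 * ll + k * log(n)
  # canonical order: component 1 = lower mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sd <- rev(sd); pi1 <- 1 - pi1; g <- 1 - g
  }
  pi1 <- min(max(pi1, 1e-12), 1 - 1e-12)
  new("MixtureFit",
      muLow = mu[1], muHigh = mu[2], sdLow = sd[1], sdHigh = sd[2],
      piLow = pi1, bic = bic, model = if (equal) "equal" else "unequal",
      logLik = ll, converged = converged, iterations = iter,
      responsibilities = pmin(pmax(g, 0), 1))
}

#' Unsupervised platform calibration of reference means
#'
#' Ports TCGA-style trained reference statistics to a new expression
#' platform without using any truth labels. Platform effects are modeled as
#' an additive per-gene shift on the log2 scale, so only the reference means
#' need re-estimation. For each MMR gene, a two-component Gaussian mixture
#' is fit to the new cohort's expression and the mean of the *higher*
#' component becomes the new MSS reference mean (the low component is the
#' expression-loss subpopulation). For the Hypermutation Predictor score,
#' the mean of the *lower* component is used (hypermutated samples score
#' high). All SD fields are copied unchanged from the input reference.
#'
#' @param mNew genes x samples log2 matrix or SummarizedExperiment on the
#'   new platform, housekeeping-normalized; >= 10 samples.
#' @param ref the trained [ReferenceStats-class].
#' @param model mixture model selection passed to [fitMixture1d()].
#' @param recalibrateSd if `TRUE`, `hyperSdMss` is additionally re-estimated
#'   from the lower mixture component of the score (responsibility-weighted
#'   SD). Off by default: the fixed-SD assumption is part of the calibration
#'   model, though it is also its known weak point.
#' @param panel optional [GenePanel-class] for coverage validation.
#' @return list with `reference` (the calibrated [ReferenceStats-class]),
#'   `fits` (named list of [MixtureFit-class], one per MMR gene plus
#'   `hyper_score`), and `report` (data.frame of mixture parameters per
#'   feature).
#' @export
calibrateReference <- function(mNew, ref, model = "auto",
                               recalibrateSd = FALSE, panel = NULL) {
  mNew <- .asExprMatrix(mNew)
  if (ncol(mNew) < 10L)
    stop("need at least 10 samples to calibrate, got ", ncol(mNew))
  if (is.null(panel))
    panel <- GenePanel(names(mmrMu(ref)), names(hyperWeights(ref)),
                       housekeepingGenes(ref))
  .stopOnPanelFailure(mNew, panel)

  fits <- list()
  new_mu <- mmrMu(ref)
  for (g in names(new_mu)) {
    fits[[g]] <- tryCatch(fitMixture1d(mNew[g, ], model = model),
                          error = function(e)
                            stop("mixture fit failed for ", g, ": ",
                                 conditionMessage(e)))
    new_mu[[g]] <- fits[[g]]@muHigh
  }

  hs <- hypermutationScoreRaw(mNew, hyperWeights(ref))
  fits$hyper_score <- tryCatch(fitMixture1d(hs, model = model),
                               error = function(e)
                                 stop("mixture fit failed for the ",
                                      "hypermutation score: ",
                                      conditionMessage(e)))
  new_hyper_mu <- fits$hyper_score@muLow

  new_hyper_sd <- hyperSdMss(ref)
  if (isTRUE(recalibrateSd)) {
    g <- fits$hyper_score@responsibilities      # P(low component)
    new_hyper_sd <- sqrt(sum(g * (hs - new_hyper_mu)^2) / sum(g))
    if (!is.finite(new_hyper_sd) || new_hyper_sd <= 0)
      stop("degenerate re-estimated hypermutation-score SD")
  }

  calibrated <- new("ReferenceStats",
                    mmrMu = new_mu, mmrSd = mmrSd(ref),
                    hyperWeights = hyperWeights(ref),
                    hyperMuMss = new_hyper_mu,
                    hyperSdMss = new_hyper_sd,
                    housekeepingGenes = housekeepingGenes(ref))
  report <- data.frame(
    feature = names(fits),
    mu_low = vapply(fits, function(f) f@muLow, numeric(1)),
    mu_high = vapply(fits, function(f) f@muHigh, numeric(1)),
    sd_low = vapply(fits, function(f) f@sdLow, numeric(1)),
    sd_high = vapply(fits, function(f) f@sdHigh, numeric(1)),
    pi_low = vapply(fits, function(f) f@piLow, numeric(1)),
    bic = vapply(fits, function(f) f@bic, numeric(1)),
    model = vapply(fits, function(f) f@model, character(1)),
    row.names = NULL)
  list(reference = calibrated, fits = fits, report = report)
}
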