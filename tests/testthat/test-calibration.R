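test_that("EM separates two well-spaced components", {
  set.seed(11)
  x <- c(rnorm(300, 0), rnorm(300, 5))
  f <- fitMixture1d(x)
  expect_gt(f@muLow, -0.2); expect_lt(f@muLow, 0.2)
  expect_gt(f@muHigh, 4.8); expect_lt(f@muHigh, 5.2)
  expect_equal(unname(mixtureWeights(f)[["low"]]), 0.5, tolerance = 0.05)
  expect_true(f@converged)
})

test_that("mixture fits are deterministic and canonically ordered", {
  set.seed(21)
  for (i in 1:5) {
    x <- rnorm(60, sample(5:15, 1), runif(1, 0.5, 2)) +
      c(rep(0, 40), rnorm(20, -3))
    f1 <- suppressWarnings(fitMixture1d(x))
    f2 <- suppressWarnings(fitMixture1d(x))
    expect_lte(f1@muLow, f1@muHigh)
    expect_identical(f1@muLow, f2@muLow)        # no hidden RNG
    expect_identical(f1@bic, f2@bic)
    expect_true(all(f1@responsibilities >= 0 & f1@responsibilities <= 1))
  }
})

test_that("unimodal data yields close component means, not a split", {
  set.seed(12)
  f <- suppressWarnings(fitMixture1d(rnorm(500)))
  expect_lt(f@muHigh - f@muLow, 1)
})

test_that("degenerate inputs are rejected", {
  expect_error(fitMixture1d(rnorm(5)), "at least 10")
  expect_error(fitMixture1d(rep(1, 50)), "zero variance")
  expect_error(fitMixture1d(c(rnorm(20), NA)), "finite")
})

test_that("EM agrees with mclust on a separated mixture", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(31)
  x <- c(rnorm(200, 2, 0.8), rnorm(100, 7, 1.2))
  f <- fitMixture1d(x, model = "unequal")
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(unname(sort(mc$parameters$mean)),
               unname(mixtureMeans(f)), tolerance = 0.05)
  expect_equal(unname(sort(sqrt(mc$parameters$variance$sigmasq))),
               unname(mixtureSds(f)), tolerance = 0.1)
})

test_that("calibration replaces means, never SDs, and ignores labels", {
  d <- normalizedCohort(syntheticConfig(seed = 201))
  ref <- estimateReference(d$m, d$truth)
  cal <- suppressWarnings(calibrateReference(d$m, ref))

  # SD invariance is bit-exact: the fixed-SD assumption of the transfer model
  expect_identical(mmrSd(cal$reference), mmrSd(ref))
  expect_identical(hyperSdMss(cal$reference), hyperSdMss(ref))
  expect_identical(hyperWeights(cal$reference), hyperWeights(ref))

  # self-calibration consistency for features with a genuine MSS bulk
  # cluster (PMS2 has no loss subpopulation and is the documented
  # unimodal failure mode, so it is held to a looser bound)
  dev <- mmrMu(cal$reference) - mmrMu(ref)
  expect_lt(max(abs(dev[c("MLH1", "MSH2", "MSH6")])), 0.3)
  expect_lt(abs(hyperMuMss(cal$reference) - hyperMuMss(ref)), 0.3)
  expect_lt(abs(dev[["PMS2"]]), 1.5)

  # MSS samples are re-centered: mean z of MLH1 in true-MSS ~ 0
  sc <- scoreCohort(d$m, cal$reference)
  expect_lt(abs(mean(sc$z_MLH1[d$truth == "MSS"])), 0.2)

  # the mixture report covers the 4 genes + the score
  expect_setequal(cal$report$feature,
                  c("MLH1", "MSH2", "MSH6", "PMS2", "hyper_score"))
})

test_that("calibration recovers an additive platform shift", {
  # paired cohorts, +1.5 on every gene; recovered per-gene shift is the
  # difference between the B and A unsupervised calibrations
  rec <- sapply(1:6, function(s) {
    pair <- generatePlatformPair(
      syntheticConfig(nSamples = 100, msiFraction = 0.2, seed = 400 + s),
      shift = 1.5)
    mA <- normalizeHousekeeping(SummarizedExperiment::assay(pair$train),
                                hkGenes())
    mB <- normalizeHousekeeping(SummarizedExperiment::assay(pair$validation),
                                hkGenes())
    refA <- estimateReference(
      mA, SummarizedExperiment::colData(pair$train)$status)
    calA <- suppressWarnings(calibrateReference(mA, refA))$reference
    calB <- suppressWarnings(calibrateReference(mB, refA))$reference
    c(mmrMu(calB) - mmrMu(calA),
      hyper = unname(hyperMuMss(calB) - hyperMuMss(calA)))
  })
  means <- rowMeans(rec)
  # MLH1 has the dominant loss subcluster: tight recovery
  expect_lt(abs(means[["MLH1"]] - 1.5), 0.2)
  expect_lt(max(abs(means[c("MSH2", "MSH6")] - 1.5)), 0.35)
  # the hyper score is invariant to a uniform shift (weights sum to 0)
  expect_lt(abs(means[["hyper"]]), 0.2)
})

test_that("uncalibrated scoring loses sensitivity that calibration restores", {
  # a platform that overreads MLH1 (+2) and compresses the signature genes
  # toward their MSS direction masks both sources of MSI evidence
  w <- hypermutationWeights()
  shift <- c(MLH1 = 2, -sign(w))
  names(shift)[-1] <- names(w)
  pair <- generatePlatformPair(syntheticConfig(seed = 77), shift = shift)
  mA <- normalizeHousekeeping(SummarizedExperiment::assay(pair$train),
                              hkGenes())
  mB <- normalizeHousekeeping(SummarizedExperiment::assay(pair$validation),
                              hkGenes())
  truthB <- SummarizedExperiment::colData(pair$validation)$status
  refA <- estimateReference(mA,
                            SummarizedExperiment::colData(pair$train)$status)
  calB <- suppressWarnings(calibrateReference(mB, refA))$reference

  raw <- scoreCohort(mB, refA)
  cal <- scoreCohort(mB, calB)
  tpr_raw <- mean(raw$call[truthB == "MSI-H"] == "MSI-H")
  tpr_cal <- mean(cal$call[truthB == "MSI-H"] == "MSI-H")
  fpr_cal <- mean(cal$call[truthB == "MSS"] == "MSI-H")
  expect_gt(tpr_cal, tpr_raw + 0.2)   # calibration restores sensitivity
  expect_lt(fpr_cal, 0.05)
})

test_that("optional SD recalibration re-estimates the score null width", {
  d <- normalizedCohort(syntheticConfig(seed = 55))
  ref <- estimateReference(d$m, d$truth)
  cal <- suppressWarnings(
    calibrateReference(d$m, ref, recalibrateSd = TRUE))
  expect_gt(hyperSdMss(cal$reference), 0)
  expect_false(identical(hyperSdMss(cal$reference), hyperSdMss(ref)))
  expect_identical(mmrSd(cal$reference), mmrSd(ref))  # MMR SDs still fixed
})

test_that("calibration needs a minimally sized cohort", {
  d <- normalizedCohort(syntheticConfig(nSamples = 30, seed = 9))
  ref <- estimateReference(d$m, d$truth)
  expect_error(calibrateReference(d$m[, 1:5], ref), "at least 10")
})
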