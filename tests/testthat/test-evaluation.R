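test_that("AUC matches brute-force pair counting", {
  # toy case enumerated by hand over all 4 (pos, neg) pairs:
  # pos {3, 2}, neg {1, 2.5}: wins 3>1, 3>2.5, 2>1; loss 2<2.5 -> 3/4
  r <- rocCurve(c(3, 2, 1, 2.5), c(1, 1, 0, 0), direction = "higher")
  expect_equal(auc(r), 0.75)

  # independent brute-force oracle on random data, with ties
  set.seed(13)
  for (i in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    pairs <- outer(s[y == 1], s[y == 0], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc(rocCurve(s, y, direction = "higher")), mean(pairs),
                 tolerance = 1e-12)
  }
})

test_that("AUC degenerate cases behave", {
  expect_equal(auc(rocCurve(c(0.01, 0.02, 0.5, 0.9), c(1, 1, 0, 0))), 1)
  expect_equal(auc(rocCurve(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))), 0.5)
  expect_error(rocCurve(1:4, c(1, 1, 1, 1)), "both classes")
  # direction flips the ranking
  s <- c(0.9, 0.1, 0.5, 0.3); y <- c(0, 1, 0, 1)
  expect_equal(auc(rocCurve(s, y, "lower")),
               1 - auc(rocCurve(s, y, "higher")))
})

test_that("trapezoidal area equals the pair-counting AUC", {
  set.seed(29)
  for (i in 1:25) {
    s <- rnorm(40)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    r <- rocCurve(s, y, direction = "higher")
    pts <- rocPoints(r)
    expect_equal(trapezoidArea(c(pts$fpr, 1), c(pts$tpr, 1)), auc(r),
                 tolerance = 1e-10)
  }
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(41)
  s <- runif(100); y <- rbinom(100, 1, 0.5)
  ours <- auc(rocCurve(s, y, direction = "higher"))
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                           quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("Wilson intervals match the closed form and the score test", {
  ci <- wilsonCi(0, 10)
  z <- qnorm(0.975)
  expect_equal(ci$lo, 0)
  expect_equal(ci$hi, z^2 / (10 + z^2), tolerance = 1e-10)  # ~0.2775
  expect_equal(ci$hi, 0.2775, tolerance = 1e-3)

  # symmetry at k = n
  ci_n <- wilsonCi(10, 10)
  expect_equal(ci_n$hi, 1)
  expect_equal(ci_n$lo, 1 - ci$hi, tolerance = 1e-12)

  # narrower with n at fixed k/n
  w1 <- wilsonCi(5, 10); w2 <- wilsonCi(50, 100)
  expect_lt(w2$hi - w2$lo, w1$hi - w1$lo)

  # cross-check against prop.test's uncorrected score interval on a lattice
  for (n in c(7, 20, 83)) for (k in unique(c(0, 1, floor(n / 2), n))) {
    ours <- wilsonCi(k, n)
    ref <- suppressWarnings(prop.test(k, n, correct = FALSE))$conf.int
    expect_equal(c(ours$lo, ours$hi), as.numeric(ref), tolerance = 1e-6)
  }
  expect_error(wilsonCi(5, 0), "n must be")
  expect_error(wilsonCi(11, 10), "k must")
})

test_that("sensitivity at 100% specificity uses a strictly clean cutoff", {
  # disjoint supports: everything detected
  r1 <- sensitivityAtFullSpecificity(c(0.001, 0.002, 0.2, 0.9), c(1, 1, 0, 0))
  expect_equal(r1$sensitivity, 1)
  # an overlapping positive is sacrificed to keep specificity exact
  r2 <- sensitivityAtFullSpecificity(c(0.001, 0.3, 0.2, 0.9), c(1, 1, 0, 0))
  expect_equal(r2$sensitivity, 0.5)
  expect_equal(r2$threshold, 0.2)

  # brute-force sweep oracle
  set.seed(59)
  for (i in 1:10) {
    p <- round(runif(40), 2)
    y <- rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    got <- sensitivityAtFullSpecificity(p, y)
    cand <- sort(unique(c(p, 1)))
    ok <- vapply(cand, function(t) sum(p[y == 0] < t) == 0, logical(1))
    best <- max(cand[ok])
    expect_equal(got$sensitivity, mean(p[y == 1] < best))
  }
})

test_that("TPR/FPR tables align ids and attach Wilson intervals", {
  d <- normalizedCohort(syntheticConfig(nSamples = 120, seed = 19))
  ref <- estimateReference(d$m, d$truth)
  sc <- scoreCohort(d$m, ref)
  truth <- setNames(d$truth, colnames(d$m))

  tab <- tprFprTable(sc, truth)
  expect_identical(tab$algorithm,
                   c("mmr_loss", "hypermutation", "msi_predictor"))
  expect_true(all(tab$tpr_lo <= tab$tpr & tab$tpr <= tab$tpr_hi))
  expect_true(all(tab$fpr_lo <= tab$fpr & tab$fpr <= tab$fpr_hi))

  # perfect calls: take p_msi as the call and truth as itself
  perfect <- data.frame(sample_id = names(truth),
                        p_mmr = ifelse(truth == "MSI-H", 1e-6, 0.9),
                        p_hyper = 0.9, p_msi = 0.9)
  perfect$p_hyper <- perfect$p_mmr
  perfect$p_msi <- perfect$p_mmr
  tab_perfect <- tprFprTable(perfect, truth)
  expect_true(all(tab_perfect$tpr == 1))
  expect_true(all(tab_perfect$fpr == 0))

  # permuted truth: rates collapse toward the overall call rate
  set.seed(3)
  shuf <- setNames(sample(truth), names(truth))
  tab_shuf <- tprFprTable(sc, shuf)
  call_rate <- mean(sc$p_msi < 0.01)
  expect_lt(abs(tab_shuf$tpr[3] - call_rate), 0.15)
  expect_lt(abs(tab_shuf$fpr[3] - call_rate), 0.15)

  expect_error(tprFprTable(sc, truth[-1]), "missing sample")
})
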