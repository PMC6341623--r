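---
title: "Predicting microsatellite instability from gene expression: models and methods"
author: "MSIscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting microsatellite instability from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

High-level microsatellite instability (MSI-H) marks tumors whose DNA
mismatch repair (MMR) machinery has failed, usually through loss of one of
MLH1, MSH2, MSH6 or PMS2. MSI-H tumors are hypermutated, immunogenic, and
disproportionately likely to respond to immune checkpoint blockade, so MSI
status is routinely tested in colorectal, gastric and endometrial cancer.
The conventional assays (IHC for MMR proteins, PCR/sequencing of
microsatellite loci) require material and workflows separate from the gene
expression profiling used to measure tumor inflammation. MSIscore predicts
MSI status directly from bulk log2 expression, so that tumor antigenicity
and immune phenotype can come off a single expression assay.

Two biologically distinct signals are exploited:

1. **MMR expression loss.** Transcriptional silencing (e.g. MLH1 promoter
   hypermethylation) depresses the mRNA of the affected MMR gene far below
   its level in MMR-proficient tumors.
2. **A downstream hypermutation signature.** Hypermutated tumors shift a
   reproducible set of transcripts up (DNA replication/metabolism, e.g.
   TYMS, WDR76, SFXN1) and down (e.g. EPM2AIP1, which shares a
   bidirectional promoter with MLH1) regardless of which MMR lesion caused
   the phenotype.

Neither signal is complete on its own: a minority of MSI-H tumors (under
10% in the cancer types above) show no MMR expression loss at all, and the
signature alone misses borderline cases. The package therefore computes
both scores and combines their evidence.

# The scores

## MMR Loss score

For each MMR gene $g$ with MSS (microsatellite-stable) reference mean
$\mu_g$ and SD $\sigma_g$, the standardized expression is
$z_g = (x_g - \mu_g)/\sigma_g$. The MMR Loss score of a sample is the most
severe loss,
$$s_{\mathrm{MMR}} = \min_{g \in \{MLH1, MSH2, MSH6, PMS2\}} z_g,$$
and its p-value is the lower-tail probability of the minimum of four
independent standard normals,
$$p_{\mathrm{MMR}} = 1 - \left(1 - \Phi(s_{\mathrm{MMR}})\right)^4 .$$
At $s_{\mathrm{MMR}} = 0$ this gives $1 - 0.5^4 = 0.9375$. Only
under-expression counts: over-expression of an MMR gene is never treated as
evidence about MSI. The independence assumption behind the
minimum-of-four correction is a deliberate simplification; the four genes
are weakly co-regulated, so the correction is slightly conservative.

## Hypermutation Predictor score

A fixed linear predictor over ten signature genes,
$$s_{\mathrm{hyp}} = \sum_{g} w_g x_g,$$
with published weights `hypermutationWeights()`. The weights sum to zero,
making the score invariant to uniform per-sample shifts (library size,
housekeeping offset), and their absolute values sum to 2, fixing the
contrast scale. Referred to its MSS null
$\mathcal N(\mu_{\mathrm{hyp}}, \sigma_{\mathrm{hyp}}^2)$, the p-value is
the upper tail: high scores indicate hypermutation.

## Combined MSI Predictor p-value

The combination rule has to satisfy two requirements: strong evidence from
either score must not be cancelled by a null result from the other, and
moderate evidence from both must accumulate. Both p-values are truncated at
the neutral point $p^* = \min(p, 0.5)$ and combined by Fisher's method
($\chi^2$ with 4 df); the result is floored by the truncated inputs:
$$p_{\mathrm{MSI}} = \min\!\left(p^*_{\mathrm{MMR}},\; p^*_{\mathrm{hyp}},\;
  S_{\chi^2_4}\!\left(-2(\ln p^*_{\mathrm{MMR}} + \ln p^*_{\mathrm{hyp}})\right)\right).$$
Truncation makes a large p-value enter as exactly neutral evidence, which
yields the first property; Fisher combination yields the second and
produces smooth, monotone decision boundaries in the
(hypermutation score, MMR Loss score) plane. The combination is symmetric,
never exceeds either (truncated) input, and improving either score can
only raise $p_{\mathrm{MSI}}$. Samples are called MSI-H when
$p_{\mathrm{MSI}} < 0.01$ by default; 0.05 and 0.001 are the conventional
flanking contour levels.

# Reference training

`estimateReference()` uses only MSS-labeled samples and estimates, per MMR
gene and for the linear predictor, the mean and a robust SD taken as
IQR$/1.349$ (the normal-theory conversion; the factor is
$2\,\Phi^{-1}(0.75)$). The IQR-based estimate keeps the reference
insensitive to mislabeled or borderline samples in the training set. At
least 8 MSS samples are required; genes with zero IQR are rejected rather
than patched. Training against the MSS label is a deployable proxy for
"non-hypermutated": mutation counts are rarely available alongside
expression, and in the cancer types of interest the two labels coincide
for the large majority of samples.

`deScreen()` reproduces the genome-wide univariate screen that nominates
signature genes: a per-gene two-group linear model (ordinary t statistics
from `limma::lmFit`, no moderation, no covariates) with Benjamini-Hochberg
FDR over all tested genes. `selectSignature()` then keeps genes
significant (FDR < 0.05) with a consistent effect sign in every cohort,
ranked by worst-case |effect|. An optional exclusion argument supports
screens refit after removing sample subsets (e.g. ultramutated tumors).
The shipped ten weights are fixed constants; the package deliberately does
not refit them.

# Cross-platform calibration

Expression platforms measure each target with different efficiency, which
on the log2 scale is well modeled as an additive per-gene shift. Only the
reference *means* therefore need re-estimation on a new platform, and this
is done without labels: `fitMixture1d()` fits a two-component Gaussian
mixture to each MMR gene (the low component is the expression-loss
subpopulation, so the **higher** mean becomes the new reference) and to
the raw Hypermutation Predictor score (hypermutated samples score high, so
the **lower** mean is taken). All SD fields are copied unchanged — the
fixed-SD assumption is part of the transfer model. It is also its known
weak point: when a validation platform has genuinely narrower MSS score
spread, the fixed SD makes calls conservative. `recalibrateSd = TRUE`
re-estimates the score SD from the lower mixture component
(responsibility-weighted) for users who prefer recalibrated boundaries.

Numerical choices in the EM:

* **Deterministic initialization** from the lower/upper halves of the
  sorted data, so calibration is reproducible without a seed and without
  random restarts.
* **Convergence** at relative log-likelihood change $< 10^{-8}$, at most
  500 iterations; non-convergence is flagged on the returned object, not
  fatal (near-unimodal data commonly drifts slowly and harmlessly).
* **Model selection** between equal- and unequal-variance models by BIC
  (`model = "auto"`), since the best 1-D model family is data-dependent.
* **Degeneracy guards:** component SDs are floored at $10^{-3}$ times the
  data SD, and a fit whose smaller component carries fewer than 3 expected
  observations is treated as an outlier spike and discarded in model
  selection when the alternative model is non-degenerate. Without this
  guard, two or three stray high values can capture a "component" and
  drag the calibrated mean far from the bulk.
* **Unimodal failure mode:** when a gene has essentially no loss
  subpopulation (PMS2 in all cohorts examined), a two-component fit must
  still split the data somewhere; the higher mean is then biased upward
  relative to the bulk mean by a fraction of an SD. The bias is
  conservative for calling loss (it can only shrink false-positive calls),
  and it cancels in platform-shift estimation because both cohorts incur
  it equally. This is documented behavior, not an error.

# The synthetic cohort generator

`generateCohort()` simulates the statistical structure the scores assume,
directly on the log2 scale (no count layer — every consumer of the data
works on log2 values, and a Gaussian log-scale model matches how the
scores treat real data):

* MSS samples draw every panel gene from $\mathcal N(10, 1)$.
* MSI-H samples (default fraction 0.25) receive a mechanism drawn from
  MLH1-loss : MSH2-loss : MSH6-loss : no-loss-hypermutated =
  0.70 : 0.12 : 0.10 : 0.08. The mechanism gene gets a $-3$ log2 loss
  shift; *all* MSI-H samples, including the no-loss class, get $\pm 1$ on
  the signature genes in the direction of each weight's sign. The mix
  reflects the observed dominance of MLH1 silencing, the rarity of
  MSH2/MSH6 events, the absence of PMS2 expression loss, and the under-10%
  no-loss minority.
* Housekeeping genes are $\mathcal N(10, 0.25^2)$; every gene then rides a
  per-sample library offset $U(-0.5, 0.5)$, so housekeeping normalization
  is genuinely exercised.
* An optional per-gene platform shift is added last;
  `generatePlatformPair()` produces an unshifted training cohort and a
  shifted validation cohort with recorded, derived seeds.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: count-level measurement noise and
mean-variance coupling, correlation among signature genes beyond the
shared hypermutation shift, ultramutated POLE/POLD1 tumors (an MSS
confounder for the signature), tumor purity variation, and heavy-tailed
per-gene distributions. Results on synthetic cohorts bound what the
algorithms can do when their model holds; they do not substitute for
validation on profiled tumors.

# Evaluation utilities

`rocCurve()` computes the AUC by tie-aware pair counting (the Mann-Whitney
statistic) and returns the full sweep; the trapezoidal area of the
returned curve equals the pair-counting value exactly, and the test suite
holds the two routes to $10^{-10}$ of each other. p-value-like scores are
evaluated with `direction = "lower"`. `wilsonCi()` implements the Wilson
score interval. `sensitivityAtFullSpecificity()` uses strict dominance:
the cutoff sits at the minimum negative-class p-value with a strict `<`
call rule, so specificity is exactly 1 without interpolation.

# Problem sizes and reproducibility

The packaged checks run, by choice, at these sizes: end-to-end
classification on 10 replicate cohorts of $n = 300$ (25% MSI-H);
platform-shift recovery on 20 paired cohorts of $n = 100$ (20% MSI-H,
+1.5 log2 shift), reported as the error of the mean recovered shift per
gene; reference recovery at $n = 500$. Averaging over replicates reports
Monte-Carlo means rather than single-cohort draws. Every random quantity
derives from an explicit integer seed; mixture calibration is
deterministic by construction. `scripts/acceptance.R` re-runs this whole
battery from a single `--seed` and writes the resulting numbers as JSON.

# Known limitations

* The MSS null for both scores is Gaussian; no empirical-null option.
* The minimum-of-four p-value assumes independent MMR genes.
* Calibration assumes an additive per-gene platform shift and fixed SDs;
  per-gene rescaling (e.g. GC- or length-dependent compression) is out of
  scope.
* The ten signature weights are fixed; `deScreen()`/`selectSignature()`
  reproduce the nomination procedure but the package does not re-derive
  weights.
* Tumor Inflammation Signature scores are accepted only as an external
  column for joint reporting; the package does not compute them.
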