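#' @include AllClasses.R expression-io.R weights.R
NULL

#' Configuration for the synthetic cohort generator
#'
#' Encodes the statistical structure the MSI scores assume, on the log2
#' scale: a dominant MSS mode per MMR gene with a low-expression MSI-H
#' subcluster; correlated up/down shifts of the ten signature genes in all
#' hypermutated samples; a minority of MSI-H samples with no MMR expression
#' loss; housekeeping genes that are tight but ride a per-sample library
#' offset; and an optional additive per-gene platform shift.
#'
#' The default mechanism mix makes MLH1 silencing the dominant cause of
#' expression loss (as observed in colon, stomach and endometrial tumors),
#' with smaller MSH2 and MSH6 fractions, no PMS2-loss class, and 8% of MSI-H
#' samples hypermutated without any MMR expression loss.
#'
#' @param nSamples cohort size (default 300).
#' @param msiFraction expected MSI-H fraction in (0,1) (default 0.25).
#' @param mechanismMix named proportions over `MLH1-loss`, `MSH2-loss`,
#'   `MSH6-loss`, `no-loss-hypermutated`; must sum to 1.
#' @param lossShift log2 shift applied to the mechanism gene in loss samples
#'   (default -3; must be negative).
#' @param hyperGeneShift magnitude of the signature-gene shift in MSI-H
#'   samples, applied in the direction of each gene's weight sign
#'   (default +1).
#' @param mssMu,mssSd MSS mean and SD of every panel gene (defaults 10, 1).
#' @param platformShift per-gene additive shift applied to the whole cohort
#'   (scalar or named vector; default 0).
#' @param nHousekeeping number of housekeeping genes (default 10).
#' @param seed integer RNG seed; mandatory for reproducibility.
#' @return a validated `list` of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nSamples = 300L,
                            msiFraction = 0.25,
                            mechanismMix = c("MLH1-loss" = 0.70,
                                             "MSH2-loss" = 0.12,
                                             "MSH6-loss" = 0.10,
                                             "no-loss-hypermutated" = 0.08),
                            lossShift = -3,
                            hyperGeneShift = 1,
                            mssMu = 10,
                            mssSd = 1,
                            platformShift = 0,
                            nHousekeeping = 10L,
                            seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a single integer seed is required")
  if (nSamples < 1L) stop("nSamples must be positive")
  if (msiFraction < 0 || msiFraction >= 1)
    stop("msiFraction must lie in [0, 1)")
  mechanisms <- c("MLH1-loss", "MSH2-loss", "MSH6-loss",
                  "no-loss-hypermutated")
  if (!setequal(names(mechanismMix), mechanisms))
    stop("mechanismMix must be named with: ",
         paste(mechanisms, collapse = ", "))
  if (abs(sum(mechanismMix) - 1) > 1e-8)
    stop("mechanismMix must sum to 1")
  if (lossShift >= 0) stop("lossShift must be negative (expression loss)")
  if (nHousekeeping < 1L) stop("nHousekeeping must be >= 1")
  structure(list(nSamples = as.integer(nSamples),
                 msiFraction = msiFraction,
                 mechanismMix = mechanismMix[mechanisms],
                 lossShift = lossShift,
                 hyperGeneShift = hyperGeneShift,
                 mssMu = mssMu, mssSd = mssSd,
                 platformShift = platformShift,
                 nHousekeeping = as.integer(nHousekeeping),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic cohort with ground truth
#'
#' Simulates log2 expression for the 14 scoring genes plus housekeeping
#' genes, with per-sample truth labels. MSS samples draw every panel gene
#' from `N(mssMu, mssSd^2)`. MSI-H samples additionally get `lossShift`
#' added to their mechanism gene (if any) and `hyperGeneShift` added to the
#' positive-weight signature genes / subtracted from the negative-weight
#' ones. Housekeeping genes are `N(mssMu, 0.25^2)`. A per-sample library
#' offset `U(-0.5, 0.5)` is added to every gene (so housekeeping
#' normalization is exercised), then the per-gene `platformShift`. Fully
#' reproducible from `cfg$seed`.
#'
#' @param cfg a [syntheticConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `log2exprs`; `colData` columns `sample_id`, `status` (`MSS`/`MSI-H`),
#'   `mechanism` (`none` for MSS), `lib_offset`; and metadata `config` and
#'   `platform_shift` (the applied named per-gene shift).
#' @examples
#' se <- generateCohort(syntheticConfig(nSamples = 50, seed = 1))
#' table(SummarizedExperiment::colData(se)$status)
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  w <- hypermutationWeights()
  hk <- sprintf("HK%02d", seq_len(cfg$nHousekeeping))
  genes <- c(.MMR_GENES, names(w), hk)
  n <- cfg$nSamples
  ids <- sprintf("S%04d", seq_len(n))

  status <- ifelse(stats::runif(n) < cfg$msiFraction, "MSI-H", "MSS")
  mechanism <- rep("none", n)
  msi <- which(status == "MSI-H")
  if (length(msi))
    mechanism[msi] <- sample(names(cfg$mechanismMix), length(msi),
                             replace = TRUE, prob = cfg$mechanismMix)

  m <- matrix(stats::rnorm(length(genes) * n, cfg$mssMu, cfg$mssSd),
              nrow = length(genes), dimnames = list(genes, ids))
  m[hk, ] <- stats::rnorm(length(hk) * n, cfg$mssMu, 0.25)

  for (i in msi) {
    mech_gene <- sub("-loss$", "", mechanism[i])
    if (mech_gene %in% .MMR_GENES)
      m[mech_gene, i] <- m[mech_gene, i] + cfg$lossShift
    m[names(w), i] <- m[names(w), i] + sign(w) * cfg$hyperGeneShift
  }

  lib_offset <- stats::runif(n, -0.5, 0.5)
  m <- sweep(m, 2L, lib_offset, "+")

  shift <- cfg$platformShift
  if (length(shift) == 1L && is.null(names(shift)))
    shift <- stats::setNames(rep(shift, length(genes)), genes)
  else {
    full <- stats::setNames(rep(0, length(genes)), genes)
    unknown <- setdiff(names(shift), genes)
    if (length(unknown))
      stop("platformShift names not in the panel: ",
           paste(unknown, collapse = ", "))
    full[names(shift)] <- shift
    shift <- full
  }
  m <- m + shift[rownames(m)]

  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2exprs = m),
    colData = S4Vectors::DataFrame(sample_id = ids, status = status,
                                   mechanism = mechanism,
                                   lib_offset = lib_offset,
                                   row.names = ids),
    metadata = list(config = cfg, platform_shift = shift))
}

#' Generate a training/validation platform pair
#'
#' Cohort A ("training") is generated with zero platform shift; cohort B
#' ("validation") with the given per-gene additive shift. The two cohorts
#' use independent seeds derived from `cfg$seed` (A: `seed`, B: `seed + 1`),
#' both recorded in each cohort's metadata.
#'
#' @param cfg a [syntheticConfig()]; its `platformShift` is ignored.
#' @param shift scalar or named per-gene additive shift for cohort B.
#' @return list with elements `train` and `validation`, each a
#'   SummarizedExperiment as from [generateCohort()].
#' @export
generatePlatformPair <- function(cfg, shift) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  cfg_a <- cfg; cfg_a$platformShift <- 0
  cfg_b <- cfg; cfg_b$platformShift <- shift
  cfg_b$seed <- cfg$seed + 1L
  list(train = generateCohort(cfg_a), validation = generateCohort(cfg_b))
}
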