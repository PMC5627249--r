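#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

## ---------------------------------------------------------------------------
## Summary statistics
## ---------------------------------------------------------------------------

#' External GWAS summary statistics
#'
#' A per-SNP table of external univariate regression coefficients together
#' with the allele and frequency metadata needed for harmonization.  Extends
#' [S4Vectors::DataFrame] with mandatory columns `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `beta_ext` and optional columns `eaf`
#' (effect-allele frequency) and `n_ext` (external sample size).  `beta_ext`
#' is interpreted on the per-SD standardized scale (trait SD per genotype
#' SD); see [standardizeBetas()] for converting per-allele coefficients.
#'
#' @export
setClass("SummaryStats", contains = "DFrame")

.validSummaryStats <- function(object) {
  msg <- NULL
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
            "beta_ext")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    msg <- c(msg, paste("missing column(s):", paste(miss, collapse = ", ")))
  if (is.null(msg)) {
    if (anyDuplicated(object$snp_id))
      msg <- c(msg, "snp_id values must be unique")
    if (!all(is.finite(object$beta_ext)))
      msg <- c(msg, "beta_ext must be finite")
    if (any(object$effect_allele == object$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    if ("eaf" %in% colnames(object)) {
      bad <- !is.na(object$eaf) & (object$eaf < 0 | object$eaf > 1)
      if (any(bad)) msg <- c(msg, "eaf must lie in [0, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SummaryStats", .validSummaryStats)

#' Construct a SummaryStats table
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels.
#' @param pos 1-based base-pair positions.
#' @param effect_allele,other_allele single-letter alleles (A/C/G/T); the
#'   published coefficient counts copies of `effect_allele`.
#' @param beta_ext per-SD standardized effect sizes.
#' @param eaf optional effect-allele frequencies in (0, 1).
#' @param n_ext optional external sample sizes.
#'
#' @return A [SummaryStats-class] object.
#' @export
SummaryStats <- function(snp_id, chrom, pos, effect_allele, other_allele,
                         beta_ext, eaf = NULL, n_ext = NULL) {
  df <- S4Vectors::DataFrame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    effect_allele = toupper(as.character(effect_allele)),
    other_allele = toupper(as.character(other_allele)),
    beta_ext = as.numeric(beta_ext))
  if (!is.null(eaf)) df$eaf <- as.numeric(eaf)
  if (!is.null(n_ext)) df$n_ext <- as.numeric(n_ext)
  new("SummaryStats", df)
}

## ---------------------------------------------------------------------------
## Genotype containers
## ---------------------------------------------------------------------------

#' Raw genotype panel
#'
#' Dosage genotypes for a target cohort, held as a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with SNPs as rows (assay `"dosage"`, entries in \[0, 2\] or `NA`) and
#' samples as columns.  Row metadata carries `snp_id`, `chrom`, `pos` and the
#' allele pair, with `allele1` the counted (coded) allele.  Variants are kept
#' in genome order (sorted by chromosome, then position).
#'
#' @export
setClass("GenotypePanel", contains = "SummarizedExperiment")

.validGenotypePanel <- function(object) {
  msg <- NULL
  rd <- SummarizedExperiment::rowData(object)
  need <- c("snp_id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    msg <- c(msg, paste("missing rowData column(s):",
                        paste(miss, collapse = ", ")))
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  if (is.null(msg)) {
    ds <- SummarizedExperiment::assay(object, "dosage")
    rng <- suppressWarnings(range(ds, na.rm = TRUE))
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      msg <- c(msg, "dosages must lie in [0, 2]")
    o <- order(rd$chrom, rd$pos)
    if (is.unsorted(o))
      msg <- c(msg, "variants must be sorted by (chrom, pos)")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("GenotypePanel", .validGenotypePanel)

#' Construct a GenotypePanel
#'
#' @param dosage numeric matrix of allele dosages, SNPs in rows and samples
#'   in columns (entries in \[0, 2\], `NA` for missing).
#' @param variants `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `allele1` (counted allele), `allele2`.
#' @param sample_ids character vector of sample identifiers.
#'
#' @return A [GenotypePanel-class]; variants are re-sorted to genome order.
#' @export
GenotypePanel <- function(dosage, variants, sample_ids) {
  stopifnot(nrow(dosage) == nrow(variants),
            ncol(dosage) == length(sample_ids))
  o <- order(variants$chrom, variants$pos)
  dosage <- dosage[o, , drop = FALSE]
  variants <- variants[o, , drop = FALSE]
  rownames(dosage) <- variants$snp_id
  colnames(dosage) <- sample_ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage),
    rowData = S4Vectors::DataFrame(variants, row.names = variants$snp_id))
  new("GenotypePanel", se)
}

#' Harmonized study
#'
#' A SNP-aligned bundle of standardized genotypes, external effect sizes,
#' phenotype and covariates, ready for weight tuning and scoring.  Extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' assay `"genotypes"` holds per-SNP standardized dosages (each row mean 0,
#' population variance 1), row metadata carries `snp_id`, `chrom`, `pos` and
#' `beta_ext` aligned to the genotype coding, and column metadata carries the
#' phenotype and covariates.
#'
#' @slot phenotypeType `"quantitative"`, `"binary"`, or `"none"`.
#' @slot covariateNames names of covariate columns in `colData`.
#'
#' @export
setClass("HarmonizedStudy", contains = "SummarizedExperiment",
         representation(phenotypeType = "character",
                        covariateNames = "character"))

.validHarmonizedStudy <- function(object) {
  msg <- NULL
  if (!"genotypes" %in% SummarizedExperiment::assayNames(object))
    return("assay 'genotypes' is required")
  g <- SummarizedExperiment::assay(object, "genotypes")
  if (anyNA(g)) msg <- c(msg, "standardized genotypes must not contain NA")
  else {
    mu <- rowMeans(g)
    if (any(abs(mu) > 1e-8))
      msg <- c(msg, "genotype rows must have mean 0 (tol 1e-8)")
    v <- rowMeans(g^2) - mu^2
    if (any(abs(v - 1) > 1e-6))
      msg <- c(msg, "genotype rows must have variance 1 (tol 1e-6)")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("snp_id", "chrom", "pos", "beta_ext") %in% colnames(rd)))
    msg <- c(msg, "rowData needs snp_id, chrom, pos, beta_ext")
  if (!object@phenotypeType %in% c("quantitative", "binary", "none"))
    msg <- c(msg, "phenotypeType must be quantitative, binary or none")
  if (is.null(msg)) TRUE else msg
}
setValidity("HarmonizedStudy", .validHarmonizedStudy)

## ---------------------------------------------------------------------------
## LD adjustment
## ---------------------------------------------------------------------------

#' Windowed LD adjustment vector
#'
#' Per-SNP sums of pairwise LD r-squared over a window of neighbouring score
#' SNPs (the self term r2 = 1 included), used to divide score weights so a
#' group of correlated SNPs jointly contributes like a single SNP.
#'
#' @slot eta numeric vector of per-SNP r-squared sums, named by SNP id when
#'   available; every value lies in \[1, 2*window + 1\].
#' @slot window integer SNP-count radius used on each side.
#'
#' @export
setClass("EtaVector",
         representation(eta = "numeric", window = "integer"))

.validEtaVector <- function(object) {
  msg <- NULL
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  if (!all(is.finite(object@eta))) msg <- c(msg, "eta must be finite")
  else {
    if (any(object@eta < 1 - 1e-8))
      msg <- c(msg, "eta must be >= 1 (self term included)")
    if (any(object@eta > 2 * object@window + 1 + 1e-8))
      msg <- c(msg, "eta cannot exceed 2*window + 1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("EtaVector", .validEtaVector)

## ---------------------------------------------------------------------------
## Boosting
## ---------------------------------------------------------------------------

#' Boosting configuration
#'
#' Hyperparameters for the gradient boosted regression trees that tune SNP
#' weights, defaulting to 2000 trees of interaction depth 5, shrinkage 0.001
#' and bag fraction 0.5 fitted over a 5-fold contiguous genome partition.
#'
#' @slot nTrees number of boosting iterations.
#' @slot interactionDepth maximum tree depth.
#' @slot shrinkage learning rate.
#' @slot bagFraction subsampling fraction per iteration.
#' @slot nFolds number of contiguous genome folds.
#' @slot treeSelection `"fixed"` (use all `nTrees`) or `"inner-cv"`
#'   (5-fold cross-validation inside each training set picks the iteration
#'   count).
#' @slot seed integer seed; fold `f` uses `seed + f`.
#'
#' @export
setClass("BoostConfig",
         representation(nTrees = "integer", interactionDepth = "integer",
                        shrinkage = "numeric", bagFraction = "numeric",
                        nFolds = "integer", treeSelection = "character",
                        seed = "integer"))

.validBoostConfig <- function(object) {
  msg <- NULL
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (object@bagFraction <= 0 || object@bagFraction > 1)
    msg <- c(msg, "bagFraction must be in (0, 1]")
  if (object@shrinkage <= 0) msg <- c(msg, "shrinkage must be > 0")
  if (object@nTrees < 1L) msg <- c(msg, "nTrees must be >= 1")
  if (!object@treeSelection %in% c("fixed", "inner-cv"))
    msg <- c(msg, "treeSelection must be 'fixed' or 'inner-cv'")
  if (is.null(msg)) TRUE else msg
}
setValidity("BoostConfig", .validBoostConfig)

#' @param nTrees,interactionDepth,shrinkage,bagFraction,nFolds,treeSelection,seed
#'   see slot documentation.
#' @return A [BoostConfig-class] object.
#' @rdname BoostConfig-class
#' @export
BoostConfig <- function(nTrees = 2000L, interactionDepth = 5L,
                        shrinkage = 0.001, bagFraction = 0.5, nFolds = 5L,
                        treeSelection = c("fixed", "inner-cv"),
                        seed = 1L) {
  new("BoostConfig", nTrees = as.integer(nTrees),
      interactionDepth = as.integer(interactionDepth),
      shrinkage = as.numeric(shrinkage),
      bagFraction = as.numeric(bagFraction),
      nFolds = as.integer(nFolds),
      treeSelection = match.arg(treeSelection),
      seed = as.integer(seed))
}

#' Weight-tuning audit table
#'
#' The full audit trail of GraBLD weight tuning: one row per score SNP with
#' the external effect (`beta_ext`), the target-cohort univariate coefficient
#' (`beta_obs`), the deviation target (`d`), its out-of-fold boosted
#' prediction (`d_hat`), the tuned signed weight (`w_hat`), the LD adjustment
#' (`eta`), the LD-corrected weight (`w_tilde`) and the contiguous fold label
#' (`fold`).  Extends [S4Vectors::DataFrame].
#'
#' @export
setClass("WeightTable", contains = "DFrame")

.validWeightTable <- function(object) {
  need <- c("snp_id", "beta_ext", "beta_obs", "d", "d_hat", "w_hat",
            "eta", "w_tilde", "fold")
  miss <- setdiff(need, colnames(object))
  if (length(miss))
    return(paste("missing column(s):", paste(miss, collapse = ", ")))
  ok <- is.na(object$eta) | is.na(object$w_tilde) |
    abs(object$w_tilde - object$w_hat / object$eta) < 1e-12 +
      1e-8 * abs(object$w_hat)
  if (!all(ok)) return("w_tilde must equal w_hat / eta")
  TRUE
}
setValidity("WeightTable", .validWeightTable)

## ---------------------------------------------------------------------------
## Scores and evaluation
## ---------------------------------------------------------------------------

#' Per-sample polygenic scores
#'
#' Holds the score values g(x_i) for a cohort together with the observed
#' trait and optional covariates, ready for evaluation and calibration.
#'
#' @slot sampleIds character sample identifiers.
#' @slot score numeric score per sample.
#' @slot trait standardized quantitative trait or 0/1 labels (may be empty).
#' @slot traitType `"quantitative"`, `"binary"`, or `"none"`.
#' @slot covariates optional numeric matrix of covariates.
#'
#' @export
setClass("ScoreSet",
         representation(sampleIds = "character", score = "numeric",
                        trait = "numeric", traitType = "character",
                        covariates = "matrixOrNULL"))

.validScoreSet <- function(object) {
  msg <- NULL
  n <- length(object@score)
  if (!all(is.finite(object@score))) msg <- c(msg, "scores must be finite")
  if (length(object@sampleIds) != n)
    msg <- c(msg, "sampleIds and score lengths differ")
  if (length(object@trait) && length(object@trait) != n)
    msg <- c(msg, "trait and score lengths differ")
  if (!is.null(object@covariates) && nrow(object@covariates) != n)
    msg <- c(msg, "covariate rows and score length differ")
  if (object@traitType == "binary" &&
      length(object@trait) && !all(object@trait %in% c(0, 1)))
    msg <- c(msg, "binary trait must be coded 0/1")
  if (is.null(msg)) TRUE else msg
}
setValidity("ScoreSet", .validScoreSet)

#' @param sampleIds,score,trait,traitType,covariates see slot documentation.
#' @return A [ScoreSet-class] object.
#' @rdname ScoreSet-class
#' @export
ScoreSet <- function(score, trait = numeric(),
                     traitType = c("none", "quantitative", "binary"),
                     sampleIds = as.character(seq_along(score)),
                     covariates = NULL) {
  traitType <- match.arg(traitType)
  if (length(trait) && traitType == "none")
    traitType <- if (all(trait %in% c(0, 1))) "binary" else "quantitative"
  new("ScoreSet", sampleIds = as.character(sampleIds),
      score = as.numeric(score), trait = as.numeric(trait),
      traitType = traitType, covariates = covariates)
}

#' Evaluation and calibration report
#'
#' @slot r2 squared correlation between score and trait (prediction R2).
#' @slot r2Model R2 of the joint linear model trait ~ score + covariates
#'   (`NA` when no covariates were supplied).
#' @slot auc area under the ROC curve (binary traits; `NA` otherwise).
#' @slot meanAbsDiff mean |predicted - observed| in trait SD units.
#' @slot decileTable per-decile calibration table.
#' @slot hlStatistic,hlPvalue Hosmer-Lemeshow chi-squared statistic and
#'   p-value (binary traits; `NA` otherwise).
#' @slot traitType `"quantitative"` or `"binary"`.
#'
#' @export
setClass("EvalReport",
         representation(r2 = "numeric", r2Model = "numeric", auc = "numeric",
                        meanAbsDiff = "numeric", decileTable = "data.frame",
                        hlStatistic = "numeric", hlPvalue = "numeric",
                        traitType = "character"))

## ---------------------------------------------------------------------------
## Simulation
## ---------------------------------------------------------------------------

#' Synthetic haplotype pool
#'
#' A founder pool of binary haplotypes with block LD structure, from which
#' diploid cohorts are drawn by random mating.
#'
#' @slot haplotypes m x H binary matrix, SNP-major (one haplotype per
#'   column).
#' @slot chrom,pos variant coordinates (a single synthetic chromosome).
#' @slot blockId integer block membership per SNP.
#' @slot targetR2 per-SNP within-block target r-squared (0 for `none`).
#' @slot freq per-SNP allele frequency used in generation.
#' @slot ldModel `"none"`, `"blocks"`, or `"mosaic"`.
#'
#' @export
setClass("HaplotypePool",
         representation(haplotypes = "matrix", chrom = "character",
                        pos = "integer", blockId = "integer",
                        targetR2 = "numeric", freq = "numeric",
                        ldModel = "character"))

#' Simulation configuration
#'
#' Study conditions for the theory experiments: a target cohort of `nTarget`
#' individuals at `mSnps` contiguous SNPs, an external summary-statistic
#' study of `nExternal` individuals drawn from the same haplotype pool, and
#' per-SNP effects drawn at each regional genetic-variance set-point in
#' `h2Grid`.
#'
#' @slot nTarget target-cohort size (default 5000).
#' @slot nExternal external-study size (default 50000).
#' @slot mSnps number of contiguous SNPs (default 450).
#' @slot h2Grid true regional genetic-variance set-points.
#' @slot nReps replicates per set-point (default 1000; `fast = TRUE`
#'   constructors use 200).
#' @slot ldModel `"none"`, `"blocks"`, or `"mosaic"`.
#' @slot blockSize SNPs per LD block (blocks model).
#' @slot withinR2 within-block r-squared levels.
#' @slot blockMix mixing fractions over `withinR2` levels.
#' @slot poolSize number of founder haplotypes (default 50000, large
#'   enough that pool-level long-range LD is negligible).
#' @slot switchRate per-SNP template switch probability (mosaic model).
#' @slot window SNP-count radius for the LD adjustment in the simulated
#'   region (default 10, twice the block size: the generator's analogue of
#'   choosing the window to cover the LD range; real-data scoring keeps
#'   the 100-SNP default of [computeEta()]).
#' @slot seed integer seed.
#'
#' @export
setClass("SimConfig",
         representation(nTarget = "integer", nExternal = "integer",
                        mSnps = "integer", h2Grid = "numeric",
                        nReps = "integer", ldModel = "character",
                        blockSize = "integer", withinR2 = "numeric",
                        blockMix = "numeric", poolSize = "integer",
                        switchRate = "numeric", window = "integer",
                        seed = "integer"))

.validSimConfig <- function(object) {
  msg <- NULL
  if (object@mSnps < 2L) msg <- c(msg, "mSnps must be >= 2")
  if (object@nReps < 1L) msg <- c(msg, "nReps must be >= 1")
  if (any(object@h2Grid < 0 | object@h2Grid > 1))
    msg <- c(msg, "h2 set-points must lie in [0, 1]")
  if (!object@ldModel %in% c("none", "blocks", "mosaic"))
    msg <- c(msg, "ldModel must be none, blocks or mosaic")
  if (length(object@withinR2) != length(object@blockMix))
    msg <- c(msg, "withinR2 and blockMix lengths differ")
  if (any(object@withinR2 < 0 | object@withinR2 > 1))
    msg <- c(msg, "withinR2 levels must lie in [0, 1]")
  if (abs(sum(object@blockMix) - 1) > 1e-8)
    msg <- c(msg, "blockMix must sum to 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("SimConfig", .validSimConfig)

#' @param nTarget,nExternal,mSnps,h2Grid,nReps,ldModel,blockSize,withinR2,blockMix,poolSize,switchRate,window,seed
#'   see slot documentation.
#' @param fast when `TRUE`, lowers `nReps` to 200 for quicker runs.
#' @return A [SimConfig-class] object.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(nTarget = 5000L, nExternal = 50000L, mSnps = 450L,
                      h2Grid = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                      nReps = 1000L,
                      ldModel = c("blocks", "none", "mosaic"),
                      blockSize = 5L,
                      withinR2 = c(0.2, 0.5, 0.8),
                      blockMix = c(5, 22, 63) / 90,
                      poolSize = 50000L, switchRate = 0.1,
                      window = 10L, seed = 1L, fast = FALSE) {
  if (fast) nReps <- min(as.integer(nReps), 200L)
  new("SimConfig", nTarget = as.integer(nTarget),
      nExternal = as.integer(nExternal), mSnps = as.integer(mSnps),
      h2Grid = as.numeric(h2Grid), nReps = as.integer(nReps),
      ldModel = match.arg(ldModel), blockSize = as.integer(blockSize),
      withinR2 = as.numeric(withinR2),
      blockMix = as.numeric(blockMix) / sum(blockMix),
      poolSize = as.integer(poolSize), switchRate = as.numeric(switchRate),
      window = as.integer(window), seed = as.integer(seed))
}

#' Theory-experiment results
#'
#' Per-replicate realized genetic variance, score/trait covariance, score
#' variance and prediction R2 for the LD-corrected summary-statistic score,
#' plus per-set-point summaries.
#'
#' @slot replicates one row per replicate: `h2`, `r2_true`, `cov_gy`,
#'   `var_g`, `pred_r2`.
#' @slot summary one row per h2 set-point with replicate means, SDs,
#'   standard errors and the recovery ratio mean(pred_r2)/mean(r2_true).
#' @slot recoveryRatio overall mean of the per-set-point recovery ratios.
#' @slot config the [SimConfig-class] used.
#'
#' @export
setClass("SimResult",
         representation(replicates = "data.frame", summary = "data.frame",
                        recoveryRatio = "numeric", config = "SimConfig"))
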