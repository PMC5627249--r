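#' Accessors for grabld containers
#'
#' `genotypeMatrix` returns the n x m samples-by-SNPs matrix used by the
#' score algebra (standardized for a [HarmonizedStudy-class], raw dosages for
#' a [GenotypePanel-class]).  `betaExt` returns the aligned external effect
#' sizes, `phenotype` the phenotype vector, `covariates` the covariate
#' matrix (or `NULL`), `snpInfo` the per-SNP metadata, `etaValues` the
#' per-SNP LD adjustment, and `scores` the per-sample score values.
#'
#' @param x a grabld object.
#' @param ... unused.
#' @return See the method descriptions above.
#' @name grabld-accessors
NULL

#' @rdname grabld-accessors
#' @export
setGeneric("genotypeMatrix", function(x, ...) standardGeneric("genotypeMatrix"))

#' @rdname grabld-accessors
#' @export
setGeneric("betaExt", function(x, ...) standardGeneric("betaExt"))

#' @rdname grabld-accessors
#' @export
setGeneric("phenotype", function(x, ...) standardGeneric("phenotype"))

#' @rdname grabld-accessors
#' @export
setGeneric("covariates", function(x, ...) standardGeneric("covariates"))

#' @rdname grabld-accessors
#' @export
setGeneric("snpInfo", function(x, ...) standardGeneric("snpInfo"))

#' @rdname grabld-accessors
#' @export
setGeneric("etaValues", function(x, ...) standardGeneric("etaValues"))

#' @rdname grabld-accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname grabld-accessors
#' @export
setMethod("genotypeMatrix", "GenotypePanel", function(x, ...)
  t(SummarizedExperiment::assay(x, "dosage")))

#' @rdname grabld-accessors
#' @export
setMethod("genotypeMatrix", "HarmonizedStudy", function(x, ...)
  t(SummarizedExperiment::assay(x, "genotypes")))

#' @rdname grabld-accessors
#' @export
setMethod("betaExt", "HarmonizedStudy", function(x, ...)
  setNames(SummarizedExperiment::rowData(x)$beta_ext,
           SummarizedExperiment::rowData(x)$snp_id))

#' @rdname grabld-accessors
#' @export
setMethod("betaExt", "SummaryStats", function(x, ...)
  setNames(x$beta_ext, x$snp_id))

#' @rdname grabld-accessors
#' @export
setMethod("phenotype", "HarmonizedStudy", function(x, ...) {
  if (x@phenotypeType == "none") return(NULL)
  SummarizedExperiment::colData(x)$phenotype
})

#' @rdname grabld-accessors
#' @export
setMethod("covariates", "HarmonizedStudy", function(x, ...) {
  if (!length(x@covariateNames)) return(NULL)
  as.matrix(as.data.frame(
    SummarizedExperiment::colData(x)[, x@covariateNames, drop = FALSE]))
})

#' @rdname grabld-accessors
#' @export
setMethod("covariates", "ScoreSet", function(x, ...) x@covariates)

#' @rdname grabld-accessors
#' @export
setMethod("snpInfo", "HarmonizedStudy", function(x, ...)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname grabld-accessors
#' @export
setMethod("snpInfo", "GenotypePanel", function(x, ...)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname grabld-accessors
#' @export
setMethod("etaValues", "EtaVector", function(x, ...) x@eta)

#' @rdname grabld-accessors
#' @export
setMethod("scores", "ScoreSet", function(x, ...)
  setNames(x@score, x@sampleIds))

#' @rdname grabld-accessors
#' @export
setMethod("phenotype", "ScoreSet", function(x, ...)
  if (length(x@trait)) x@trait else NULL)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "HarmonizedStudy", function(object) {
  cat(sprintf("HarmonizedStudy: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
  cat(sprintf("  phenotype: %s; covariates: %d\n", object@phenotypeType,
              length(object@covariateNames)))
  chr <- unique(SummarizedExperiment::rowData(object)$chrom)
  cat(sprintf("  chromosomes: %s\n", paste(head(chr, 8), collapse = ", ")))
  invisible(NULL)
})

setMethod("show", "EtaVector", function(object) {
  cat(sprintf("EtaVector: %d SNPs, window +/-%d SNPs\n",
              length(object@eta), object@window))
  cat(sprintf("  eta range [%.3f, %.3f], mean %.3f\n",
              min(object@eta), max(object@eta), mean(object@eta)))
  invisible(NULL)
})

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet: %d samples (trait: %s)\n", length(object@score),
              object@traitType))
  cat(sprintf("  score mean %.4g, sd %.4g\n", mean(object@score),
              sd(object@score)))
  invisible(NULL)
})

setMethod("show", "BoostConfig", function(object) {
  cat(sprintf(paste0("BoostConfig: %d trees, depth %d, shrinkage %g, ",
                     "bag %g, %d folds, selection %s, seed %d\n"),
              object@nTrees, object@interactionDepth, object@shrinkage,
              object@bagFraction, object@nFolds, object@treeSelection,
              object@seed))
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: n=%d, N=%d, m=%d, LD model %s, %d reps/set-point\n",
              object@nTarget, object@nExternal, object@mSnps,
              object@ldModel, object@nReps))
  cat(sprintf("  h2 grid: %s; window %d; seed %d\n",
              paste(object@h2Grid, collapse = ", "), object@window,
              object@seed))
  invisible(NULL)
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d replicates over %d h2 set-points\n",
              nrow(object@replicates), nrow(object@summary)))
  print(object@summary, digits = 4)
  cat(sprintf("  overall recovery ratio: %.4f\n", object@recoveryRatio))
  invisible(NULL)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  cat(sprintf("  prediction R2: %.4f\n", object@r2))
  if (!is.na(object@r2Model))
    cat(sprintf("  joint-model R2 (score + covariates): %.4f\n",
                object@r2Model))
  if (!is.na(object@auc)) cat(sprintf("  AUC: %.4f\n", object@auc))
  if (!is.na(object@meanAbsDiff))
    cat(sprintf("  mean |pred - obs|: %.4f SD\n", object@meanAbsDiff))
  if (!is.na(object@hlStatistic))
    cat(sprintf("  Hosmer-Lemeshow: X2 = %.3f, p = %.4g\n",
                object@hlStatistic, object@hlPvalue))
  invisible(NULL)
})

setMethod("show", "HaplotypePool", function(object) {
  cat(sprintf("HaplotypePool: %d SNPs x %d haplotypes (%s LD model)\n",
              nrow(object@haplotypes), ncol(object@haplotypes),
              object@ldModel))
  invisible(NULL)
})
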