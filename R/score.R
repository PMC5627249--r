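#' Compute polygenic scores
#'
#' `g(x_i) = sum_j x_ij * w_j` over standardized genotypes, with `w` the
#' LD-corrected weight vector.  The score is linear in the weights.
#'
#' @param x a [HarmonizedStudy-class], or a samples-by-SNPs standardized
#'   genotype matrix.
#' @param weights length-m numeric weight vector (typically `w_tilde` from a
#'   [WeightTable-class]), or a [WeightTable-class] itself.
#' @param trait optional observed trait for evaluation (taken from the
#'   study when `x` is a [HarmonizedStudy-class]).
#' @param covariates optional covariate matrix carried into the score set.
#'
#' @return A [ScoreSet-class].
#' @export
computeScore <- function(x, weights, trait = NULL, covariates = NULL) {
  if (is(weights, "WeightTable")) {
    w <- if (all(is.na(weights$w_tilde))) weights$w_hat else weights$w_tilde
  } else w <- as.numeric(weights)
  if (is(x, "HarmonizedStudy")) {
    if (is.null(trait) && x@phenotypeType != "none") trait <- phenotype(x)
    if (is.null(covariates)) covariates <- covariates(x)
    ids <- colnames(x)
    x <- genotypeMatrix(x)
  } else {
    x <- as.matrix(x)
    ids <- rownames(x)
  }
  if (ncol(x) != length(w))
    stop("genotype columns (", ncol(x), ") and weights (", length(w),
         ") do not match")
  g <- drop(x %*% w)
  if (is.null(ids)) ids <- as.character(seq_along(g))
  ScoreSet(score = g, trait = if (is.null(trait)) numeric() else trait,
           sampleIds = ids, covariates = covariates)
}

#' Prediction R-squared of a score
#'
#' The squared Pearson correlation between score and trait,
#' `Cov(g, y)^2 / (Var(g) Var(y))`.  When covariates are present the
#' R-squared of the joint linear model `trait ~ score + covariates` is also
#' reported.
#'
#' @param scoreSet a [ScoreSet-class] with a quantitative trait.
#'
#' @return List with `r2` and `r2_model` (`NA` without covariates).
#' @export
evaluateR2 <- function(scoreSet) {
  stopifnot(is(scoreSet, "ScoreSet"))
  y <- scoreSet@trait
  if (!length(y)) stop("score set has no trait to evaluate against")
  g <- scoreSet@score
  if (var(g) == 0) {
    warning("score has zero variance; r2 defined as 0")
    r2 <- 0
  } else r2 <- cor(g, y)^2
  r2Model <- NA_real_
  if (!is.null(scoreSet@covariates)) {
    fit <- lm(y ~ g + scoreSet@covariates)
    r2Model <- summary(fit)$r.squared
  }
  list(r2 = r2, r2_model = r2Model)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted one half (the Mann-Whitney identity), computed via
#' \pkg{pROC}.
#'
#' @param scoreSet a [ScoreSet-class] with 0/1 trait labels.
#'
#' @return AUC value in \[0, 1\].
#' @export
evaluateAUC <- function(scoreSet) {
  stopifnot(is(scoreSet, "ScoreSet"))
  y <- scoreSet@trait
  if (!length(y) || !all(y %in% c(0, 1)))
    stop("AUC requires 0/1 trait labels")
  if (length(unique(y)) < 2L)
    stop("AUC undefined: only one class present")
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = scoreSet@score,
                                 levels = c(0, 1), direction = "<",
                                 quiet = TRUE)))
}

#' Mean absolute difference between predicted and observed trait
#'
#' @param predicted,observed equal-length numeric vectors on the
#'   standardized trait scale.
#'
#' @return Mean of `|predicted - observed|` in trait SD units.
#' @export
meanAbsDifference <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  mean(abs(predicted - observed))
}

#' Evaluate a score set
#'
#' Convenience wrapper producing an [EvalReport-class]: prediction
#' R-squared (quantitative), AUC (binary), mean absolute difference and the
#' decile calibration table (with Hosmer-Lemeshow test for binary traits).
#' `predicted` defaults to the raw score; pass calibrated predictions (see
#' [calibrateLinear()]) for meaningful calibration metrics.
#'
#' @param scoreSet a [ScoreSet-class] with a trait.
#' @param predicted optional vector of calibrated predictions on the trait
#'   scale (defaults to the raw score).
#'
#' @return An [EvalReport-class].
#' @export
evaluateScores <- function(scoreSet, predicted = NULL) {
  stopifnot(is(scoreSet, "ScoreSet"))
  y <- scoreSet@trait
  if (!length(y)) stop("score set has no trait to evaluate against")
  if (is.null(predicted)) predicted <- scoreSet@score
  binary <- scoreSet@traitType == "binary"
  r2 <- NA_real_; r2Model <- NA_real_; auc <- NA_real_
  mad <- NA_real_; hlS <- NA_real_; hlP <- NA_real_
  if (binary) {
    auc <- evaluateAUC(scoreSet)
  } else {
    ev <- evaluateR2(scoreSet)
    r2 <- ev$r2; r2Model <- ev$r2_model
    mad <- meanAbsDifference(predicted, y)
  }
  cal <- calibrationByDecile(predicted, y, binary = binary)
  if (binary) { hlS <- cal$hl_statistic; hlP <- cal$hl_pvalue }
  new("EvalReport", r2 = r2, r2Model = r2Model, auc = auc,
      meanAbsDiff = mad, decileTable = cal$decile_table,
      hlStatistic = hlS, hlPvalue = hlP,
      traitType = scoreSet@traitType)
}

#' Write scores / evaluation reports
#'
#' @param scoreSet a [ScoreSet-class].
#' @param path output path.
#' @param calibrated optional calibrated predictions written alongside.
#'
#' @return `path`, invisibly.
#' @export
writeScores <- function(scoreSet, path, calibrated = NULL) {
  df <- data.frame(sample_id = scoreSet@sampleIds, score = scoreSet@score)
  if (!is.null(calibrated)) df$calibrated_score <- calibrated
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param report an [EvalReport-class].
#' @rdname writeScores
#' @export
writeEvalReport <- function(report, path) {
  out <- list(trait_type = report@traitType, r2 = report@r2,
              r2_model = report@r2Model, auc = report@auc,
              mean_abs_diff = report@meanAbsDiff,
              hl_statistic = report@hlStatistic,
              hl_pvalue = report@hlPvalue,
              decile_table = report@decileTable)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
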