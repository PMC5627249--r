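#' Per-SNP univariate coefficients in the target cohort
#'
#' Computes `beta_obs_j = x_j' y / n` on standardized genotype columns,
#' identical to the univariate least-squares slope of the standardized
#' phenotype on each standardized SNP.  Binary 0/1 labels are standardized
#' to mean 0, population variance 1 before the product, so quantitative and
#' binary traits share one scale (the linear-probability slope).
#'
#' @param x a [HarmonizedStudy-class] or samples-by-SNPs standardized matrix.
#' @param y phenotype vector: standardized quantitative values or 0/1
#'   labels (taken from the study when `x` is a [HarmonizedStudy-class]).
#'
#' @return Named numeric vector of per-SNP coefficients.
#' @export
computeBetaObs <- function(x, y = NULL) {
  if (is(x, "HarmonizedStudy")) {
    if (is.null(y)) y <- phenotype(x)
    x <- genotypeMatrix(x)
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("a phenotype vector is required")
  if (length(y) != nrow(x))
    stop("phenotype length (", length(y), ") does not match sample count (",
         nrow(x), ")")
  if (all(y %in% c(0, 1))) {
    y <- y - mean(y)
    s <- sqrt(mean(y^2))
    if (s == 0) stop("phenotype is constant")
    y <- y / s
  }
  drop(crossprod(x, y)) / nrow(x)
}

#' Deviation of observed from external effects
#'
#' Builds the boosting target `d_j = (beta_obs_j - beta_ext_j) *
#' sign(beta_ext_j)`: the signed shrinkage of the target-cohort effect
#' relative to the external effect along the external direction.  `d = 0`
#' means the external coefficient is reproduced exactly; when directions
#' agree, `d = |beta_obs| - |beta_ext|`.
#'
#' @param beta_obs,beta_ext equal-length numeric vectors.
#'
#' @return Numeric deviation vector (0 where `beta_ext` is 0; such SNPs
#'   carry no external direction and are excluded from boosting upstream).
#' @export
computeDeviation <- function(beta_obs, beta_ext) {
  if (length(beta_obs) != length(beta_ext))
    stop("beta_obs and beta_ext lengths differ")
  (beta_obs - beta_ext) * sign(beta_ext)
}

#' Contiguous genome folds
#'
#' Partitions `m` SNPs (already in genome order) into `k` contiguous blocks
#' whose sizes differ by at most one, larger blocks first.  Block boundaries
#' may split chromosomes; contiguity is what prevents LD spillover between
#' a SNP's own fold and the folds its weight model is trained on.
#'
#' @param m SNP count.
#' @param k fold count.
#'
#' @return Integer vector of fold labels in `1..k`.
#' @export
assignFolds <- function(m, k) {
  m <- as.integer(m); k <- as.integer(k)
  if (k > m) stop("more folds (", k, ") than SNPs (", m, ")")
  if (k < 1L) stop("k must be >= 1")
  sizes <- rep(m %/% k, k)
  extra <- m %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Out-of-fold boosted deviation predictions
#'
#' For each fold `f`, fits gradient boosted regression trees (squared-error
#' loss) of the deviation `d` on the predictor columns `z` using every SNP
#' *not* in fold `f`, and predicts `d_hat` for the SNPs in `f`.  A SNP's own
#' observed coefficient therefore never informs its own weight.  Fold `f`
#' uses RNG seed `seed + f`, so refitting one fold is unaffected by changes
#' in the others.
#'
#' @param z numeric matrix of SNP-level predictors (default usage: the
#'   single column `|beta_ext|`).
#' @param d numeric deviation targets.
#' @param fold integer fold labels from [assignFolds()].
#' @param config a [BoostConfig-class].
#'
#' @return List with `d_hat` (out-of-fold predictions) and `n_trees_used`
#'   (per-fold iteration counts after tree selection).
#' @export
fitBoostedDeviation <- function(z, d, fold, config = BoostConfig()) {
  z <- as.matrix(z)
  if (is.null(colnames(z))) colnames(z) <- paste0("z", seq_len(ncol(z)))
  m <- length(d)
  stopifnot(nrow(z) == m, length(fold) == m)
  if (!all(is.finite(z))) stop("predictor columns must be finite")
  folds <- sort(unique(fold))
  if (length(folds) < 2L) stop("at least 2 folds are required")

  dHat <- rep(NA_real_, m)
  used <- integer(length(folds))
  for (i in seq_along(folds)) {
    f <- folds[i]
    tr <- which(fold != f)
    te <- which(fold == f)
    if (length(tr) < config@interactionDepth + 1L)
      stop("degenerate fit: fold ", f, " leaves only ", length(tr),
           " training SNPs")
    params <- list(objective = "reg:squarederror",
                   max_depth = config@interactionDepth,
                   eta = config@shrinkage,
                   subsample = config@bagFraction,
                   lambda = 0, alpha = 0, gamma = 0,
                   min_child_weight = 10,
                   base_score = mean(d[tr]),
                   nthread = 1,
                   seed = config@seed + i)
    dtrain <- xgboost::xgb.DMatrix(z[tr, , drop = FALSE], label = d[tr],
                                   nthread = 1)
    nrounds <- config@nTrees
    if (config@treeSelection == "inner-cv") {
      cv <- xgboost::xgb.cv(params = params, data = dtrain,
                            nrounds = config@nTrees, nfold = 5,
                            verbose = FALSE)
      rmse <- cv$evaluation_log$test_rmse_mean
      nrounds <- which.min(rmse)
    }
    bst <- xgboost::xgb.train(params = params, data = dtrain,
                              nrounds = nrounds, verbose = 0)
    dHat[te] <- predict(bst, xgboost::xgb.DMatrix(z[te, , drop = FALSE],
                                                  nthread = 1))
    used[i] <- nrounds
  }
  list(d_hat = dHat, n_trees_used = used)
}

#' Tuned signed weights from external effects and fitted deviations
#'
#' Under the adopted convention, `w_hat_j = sign(beta_ext_j) *
#' (|beta_ext_j| + d_hat_j)`: when the fitted deviation equals the true
#' deviation and directions agree, the weight recovers
#' `sign(beta_ext_j) * |beta_obs_j|` — external direction, target-population
#' magnitude.  `literalEq4 = TRUE` instead applies the printed composition
#' `(beta_ext - d_hat) * sign(beta_ext)` verbatim (kept for comparison; it
#' amplifies attenuated SNPs).
#'
#' @param beta_ext,d_hat equal-length numeric vectors.
#' @param literalEq4 use the literal printed composition.
#' @param truncateNegative set weights whose tuned magnitude
#'   `|beta_ext| + d_hat` is negative to zero instead of keeping the
#'   sign-crossed weight.
#'
#' @return Numeric weight vector (0 where `beta_ext` is 0).
#' @export
computeWeights <- function(beta_ext, d_hat, literalEq4 = FALSE,
                           truncateNegative = FALSE) {
  if (length(beta_ext) != length(d_hat))
    stop("beta_ext and d_hat lengths differ")
  d_hat <- ifelse(is.na(d_hat), 0, d_hat)
  if (literalEq4) {
    w <- (beta_ext - d_hat) * sign(beta_ext)
  } else {
    mag <- abs(beta_ext) + d_hat
    if (truncateNegative) mag <- pmax(mag, 0)
    w <- sign(beta_ext) * mag
  }
  w
}

#' Tune score weights with gradient boosted regression trees
#'
#' The full weight-tuning stage: computes target-cohort univariate
#' coefficients, builds the deviation target, assigns contiguous genome
#' folds, fits the boosted deviation model out-of-fold, and composes the
#' tuned weights.  SNPs with `beta_ext = 0` are excluded from boosting and
#' receive weight 0.  LD adjustment is a separate, subsequent step
#' ([computeEta()] / [applyLDCorrection()]): correcting for LD before
#' boosting would discard association-strength information.
#'
#' @param study a [HarmonizedStudy-class] with a phenotype.
#' @param config a [BoostConfig-class].
#' @param z optional SNP-level predictor matrix (default: the single column
#'   `|beta_ext|`); additional annotation columns may be supplied.
#' @param literalEq4,truncateNegative passed to [computeWeights()].
#'
#' @return A [WeightTable-class] (with `eta`/`w_tilde` set to `NA` until
#'   [ldAdjustWeights()] fills them).
#' @export
boostWeights <- function(study, config = BoostConfig(), z = NULL,
                         literalEq4 = FALSE, truncateNegative = FALSE) {
  stopifnot(is(study, "HarmonizedStudy"))
  if (study@phenotypeType == "none")
    stop("study has no phenotype; weight tuning needs a calibration trait")
  betaExtV <- unname(betaExt(study))
  betaObs <- unname(computeBetaObs(study))
  d <- computeDeviation(betaObs, betaExtV)
  m <- length(betaExtV)
  fold <- assignFolds(m, config@nFolds)
  if (is.null(z)) z <- matrix(abs(betaExtV), ncol = 1,
                              dimnames = list(NULL, "abs_beta_ext"))
  z <- as.matrix(z)

  dHat <- rep(NA_real_, m)
  inc <- which(betaExtV != 0)
  if (length(inc) < m)
    message("boostWeights: ", m - length(inc),
            " SNP(s) with beta_ext = 0 excluded from boosting (weight 0)")
  fit <- fitBoostedDeviation(z[inc, , drop = FALSE], d[inc], fold[inc],
                             config)
  dHat[inc] <- fit$d_hat
  wHat <- computeWeights(betaExtV, dHat, literalEq4 = literalEq4,
                         truncateNegative = truncateNegative)
  info <- snpInfo(study)
  new("WeightTable", S4Vectors::DataFrame(
    snp_id = info$snp_id, beta_ext = betaExtV, beta_obs = betaObs,
    d = d, d_hat = dHat, w_hat = wHat,
    eta = NA_real_, w_tilde = NA_real_, fold = fold,
    row.names = info$snp_id))
}

#' Fill the LD-corrected weights of a WeightTable
#'
#' Computes the windowed sum-of-r2 adjustment on the study genotypes and
#' divides the tuned weights by it.
#'
#' @param wt a [WeightTable-class] from [boostWeights()].
#' @param study the [HarmonizedStudy-class] the weights belong to (its
#'   genotypes supply the LD estimates).
#' @param window SNP-count radius (default 100).
#'
#' @return The completed [WeightTable-class].
#' @export
ldAdjustWeights <- function(wt, study, window = 100L) {
  stopifnot(nrow(wt) == nrow(study))
  eta <- computeEta(study, window = window)
  df <- as(wt, "DFrame")
  df$eta <- unname(etaValues(eta))
  df$w_tilde <- applyLDCorrection(df$w_hat, df$eta)
  new("WeightTable", df)
}
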