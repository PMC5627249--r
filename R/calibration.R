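#' Linear recalibration of scores
#'
#' Least-squares fit of the observed trait on the score (and covariates) in
#' a training set.  The returned transformation is applied to validation
#' scores before calibration metrics are computed; the training set must be
#' disjoint from the evaluation set (caller-enforced).  Perfectly collinear
#' covariates are dropped by the least-squares fit with a warning.
#'
#' @param trainScores a [ScoreSet-class] with trait (and optional
#'   covariates) from the training set.
#'
#' @return List with `intercept`, `slope`, `coefficients` (full named
#'   vector) and `predict(score, covariates)`, a function applying the
#'   fitted transformation.
#' @export
calibrateLinear <- function(trainScores) {
  stopifnot(is(trainScores, "ScoreSet"))
  y <- trainScores@trait
  if (!length(y)) stop("training score set has no trait")
  g <- trainScores@score
  cv <- trainScores@covariates
  fit <- if (is.null(cv)) lm(y ~ g) else lm(y ~ g + cv)
  cf <- coef(fit)
  if (anyNA(cf)) {
    warning("collinear covariate(s) dropped from the calibration model")
    cf[is.na(cf)] <- 0
  }
  names(cf) <- sub("^cv", "", names(cf))
  predictFun <- function(score, covariates = NULL) {
    out <- cf[1] + cf["g"] * score
    if (!is.null(cv)) {
      if (is.null(covariates))
        stop("calibration model includes covariates; supply them")
      covariates <- as.matrix(covariates)
      out <- out + drop(covariates %*% cf[-(1:2)])
    }
    unname(out)
  }
  list(intercept = unname(cf[1]), slope = unname(cf["g"]),
       coefficients = cf, predict = predictFun)
}

#' Decile calibration table (and Hosmer-Lemeshow test)
#'
#' Ranks samples into 10 equal-count bins by predicted value (stable
#' ties-by-order ranking), and reports per-bin mean predicted, mean
#' observed, their difference, and a normal-approximation 95\% CI for the
#' difference.  For binary traits the Hosmer-Lemeshow statistic
#' `sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))` is added with a
#' chi-squared p-value on G-2 degrees of freedom; bins whose expected count
#' is degenerate (0 or n_g) are merged with a neighbour.
#'
#' @param predicted numeric predictions (probabilities for binary traits).
#' @param observed observed trait values or 0/1 labels.
#' @param binary treat the trait as binary.
#' @param nBins number of quantile bins (default 10).
#'
#' @return List with `decile_table` (data.frame: `decile`, `n`,
#'   `mean_predicted`, `mean_observed`, `difference`, `ci_lower`,
#'   `ci_upper`) and, for binary traits, `hl_statistic` and `hl_pvalue`.
#' @export
calibrationByDecile <- function(predicted, observed, binary = FALSE,
                                nBins = 10L) {
  stopifnot(length(predicted) == length(observed))
  n <- length(predicted)
  if (n < nBins) stop("need at least ", nBins, " samples")
  o <- order(predicted)  # stable: ties keep input order
  sizes <- diff(round(seq(0, n, length.out = nBins + 1)))
  binOf <- integer(n)
  binOf[o] <- rep(seq_len(nBins), times = sizes)

  tab <- do.call(rbind, lapply(seq_len(nBins), function(b) {
    i <- which(binOf == b)
    mp <- mean(predicted[i]); mo <- mean(observed[i])
    dif <- mo - mp
    se <- if (binary) sqrt(max(mp * (1 - mp), 0) / length(i)) else
      sd(observed[i] - predicted[i]) / sqrt(length(i))
    data.frame(decile = b, n = length(i), mean_predicted = mp,
               mean_observed = mo, difference = dif,
               ci_lower = dif - 1.96 * se, ci_upper = dif + 1.96 * se)
  }))
  out <- list(decile_table = tab)
  if (binary) {
    hl <- .hosmerLemeshow(obs = tab$mean_observed * tab$n,
                          exp = tab$mean_predicted * tab$n,
                          ng = tab$n)
    out$hl_statistic <- hl$statistic
    out$hl_pvalue <- hl$p_value
    out$hl_df <- hl$df
  }
  out
}

#' Plot a decile calibration table
#'
#' Difference between mean observed and mean predicted trait per decile,
#' with 95\% CIs, against the mean predicted value — the standard visual
#' check that high- and low-score individuals are neither over- nor
#' under-predicted.
#'
#' @param report an [EvalReport-class] (or a decile table data.frame).
#' @param path optional PNG path; when `NULL`, draws on the active device.
#'
#' @return The decile table, invisibly.
#' @export
plotCalibration <- function(report, path = NULL) {
  tab <- if (is(report, "EvalReport")) report@decileTable else
    as.data.frame(report)
  if (!is.null(path)) {
    grDevices::png(path, width = 720, height = 540)
    on.exit(grDevices::dev.off())
  }
  ylim <- range(tab$ci_lower, tab$ci_upper, 0)
  plot(tab$mean_predicted, tab$difference, pch = 19, ylim = ylim,
       xlab = "mean predicted (decile)",
       ylab = "observed - predicted",
       main = "Decile calibration")
  graphics::arrows(tab$mean_predicted, tab$ci_lower,
                   tab$mean_predicted, tab$ci_upper,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 2)
  invisible(tab)
}

## HL statistic from per-bin observed counts, expected counts and sizes.
## Bins with degenerate expected counts are merged with the neighbour below
## (or above, for the first bin).
.hosmerLemeshow <- function(obs, exp, ng) {
  i <- 1L
  while (i <= length(ng)) {
    if (exp[i] <= 0 || exp[i] >= ng[i]) {
      j <- if (i == 1L) 2L else i - 1L
      if (length(ng) < 2L) stop("cannot compute HL statistic on one bin")
      message("calibrationByDecile: merged degenerate bin ", i,
              " with neighbour")
      obs[j] <- obs[j] + obs[i]; exp[j] <- exp[j] + exp[i]
      ng[j] <- ng[j] + ng[i]
      obs <- obs[-i]; exp <- exp[-i]; ng <- ng[-i]
      i <- 1L
    } else i <- i + 1L
  }
  stat <- sum((obs - exp)^2 / (exp * (1 - exp / ng)))
  df <- max(length(ng) - 2L, 1L)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df)
}
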