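test_that("scores are the weighted genotype sums", {
  x <- matrix(c(1, -1, 0.5, 2, 0, -0.5), nrow = 2, byrow = TRUE)
  w <- c(0.1, -0.2, 0.3)
  ss <- computeScore(x, w)
  # hand-computed dot products
  expect_equal(unname(scores(ss)),
               c(1 * 0.1 + -1 * -0.2 + 0.5 * 0.3,
                 2 * 0.1 + 0 * -0.2 + -0.5 * 0.3))
  # zero weights give zero scores
  expect_equal(unname(scores(computeScore(x, rep(0, 3)))), c(0, 0))
  # mismatched weight length is an error
  expect_error(computeScore(x, c(0.1, 0.2)), "do not match")
})

test_that("duplicated SNPs at weight w/5 contribute like one SNP at w", {
  set.seed(40)
  col <- rnorm(30)
  x5 <- matrix(rep(col, 5), ncol = 5)
  w <- 0.4
  single <- col * w
  five <- scores(computeScore(x5, rep(w / 5, 5)))
  expect_equal(unname(five), single, tolerance = 1e-12)
})

test_that("prediction R2 is the squared Pearson correlation", {
  set.seed(41)
  y <- rnorm(30)
  expect_equal(evaluateR2(ScoreSet(score = y, trait = y))$r2, 1)
  # fixed 6-element vectors against the textbook formula
  g <- c(0.2, -1.1, 0.4, 0.9, -0.3, 0.8)
  y6 <- c(0.1, -0.9, 0.6, 0.2, 0.3, 0.5)
  covgy <- mean(g * y6) - mean(g) * mean(y6)
  oracle <- covgy^2 / ((mean(g^2) - mean(g)^2) * (mean(y6^2) - mean(y6)^2))
  expect_equal(evaluateR2(ScoreSet(score = g, trait = y6))$r2, oracle,
               tolerance = 1e-12)
  # independent score: near zero at large n
  set.seed(42)
  n <- 20000
  r2null <- evaluateR2(ScoreSet(score = rnorm(n), trait = rnorm(n)))$r2
  expect_lt(r2null, 0.001)
  # zero-variance score is defined as 0 with a warning
  expect_warning(r0 <- evaluateR2(ScoreSet(score = rep(1, 10),
                                           trait = rnorm(10)))$r2,
                 "zero variance")
  expect_equal(r0, 0)
})

test_that("joint-model R2 is reported alongside Eq-9 R2 with covariates", {
  set.seed(43)
  n <- 200
  g <- rnorm(n); cv <- matrix(rnorm(n), ncol = 1)
  y <- 0.5 * g + 0.8 * cv[, 1] + rnorm(n, 0, 0.5)
  ev <- evaluateR2(ScoreSet(score = g, trait = y, covariates = cv))
  expect_equal(ev$r2_model, summary(lm(y ~ g + cv))$r.squared,
               tolerance = 1e-12)
  expect_lt(ev$r2, ev$r2_model)
})

test_that("AUC equals exhaustive pair counting with half-weight ties", {
  lab <- c(0, 0, 1, 1)
  s1 <- c(1, 2, 3, 4)
  expect_equal(evaluateAUC(ScoreSet(score = s1, trait = lab,
                                    traitType = "binary")), 1)
  # one tie across the classes
  s2 <- c(1, 2, 2, 4)
  expect_equal(evaluateAUC(ScoreSet(score = s2, trait = lab,
                                    traitType = "binary")),
               allPairsAUC(s2, lab))
  set.seed(44)
  s3 <- sample(1:5, 40, replace = TRUE)
  lab3 <- rbinom(40, 1, 0.5)
  if (length(unique(lab3)) == 2)
    expect_equal(evaluateAUC(ScoreSet(score = s3, trait = lab3,
                                      traitType = "binary")),
                 allPairsAUC(s3, lab3))
  # null case at large n
  set.seed(45)
  aucNull <- evaluateAUC(ScoreSet(score = rnorm(20000),
                                  trait = rbinom(20000, 1, 0.5),
                                  traitType = "binary"))
  expect_lt(abs(aucNull - 0.5), 0.02)
  # one class absent is an undefined-metric error
  expect_error(evaluateAUC(ScoreSet(score = 1:4, trait = rep(1, 4),
                                    traitType = "binary")), "one class")
})

test_that("scale invariance and label-flip antisymmetry hold", {
  set.seed(46)
  n <- 500
  x <- stdMatrix(n, 10, seed = 46)
  w <- rnorm(10, 0, 0.1)
  y <- drop(x %*% w) + rnorm(n)
  lab <- as.numeric(y > 0)
  for (c in c(0.5, 3)) {
    s1 <- computeScore(x, w, trait = y)
    s2 <- computeScore(x, w * c, trait = y)
    expect_equal(evaluateR2(s2)$r2, evaluateR2(s1)$r2, tolerance = 1e-12)
    b1 <- ScoreSet(score = scores(s1), trait = lab, traitType = "binary")
    b2 <- ScoreSet(score = scores(s2), trait = lab, traitType = "binary")
    expect_equal(evaluateAUC(b2), evaluateAUC(b1), tolerance = 1e-12)
  }
  flip <- ScoreSet(score = drop(x %*% w), trait = 1 - lab,
                   traitType = "binary")
  keep <- ScoreSet(score = drop(x %*% w), trait = lab,
                   traitType = "binary")
  expect_equal(evaluateAUC(flip), 1 - evaluateAUC(keep), tolerance = 1e-12)
})

test_that("linear calibration recovers the least-squares transformation", {
  set.seed(47)
  y <- rnorm(40)
  idFit <- calibrateLinear(ScoreSet(score = y, trait = y))
  expect_equal(idFit$slope, 1, tolerance = 1e-10)
  expect_equal(idFit$intercept, 0, tolerance = 1e-10)
  halfFit <- calibrateLinear(ScoreSet(score = 2 * y, trait = y))
  expect_equal(halfFit$slope, 0.5, tolerance = 1e-10)

  # fixed 8-point set against the normal equations
  g8 <- c(0.3, -1.2, 0.8, 1.5, -0.4, 0.1, -0.9, 0.6)
  y8 <- c(0.2, -0.8, 0.9, 1.1, -0.6, 0.3, -0.7, 0.4)
  fit <- calibrateLinear(ScoreSet(score = g8, trait = y8))
  X <- cbind(1, g8)
  bhat <- unname(drop(solve(crossprod(X), crossprod(X, y8))))
  expect_equal(c(fit$intercept, fit$slope), bhat, tolerance = 1e-10)
  expect_equal(fit$predict(g8), drop(X %*% bhat), tolerance = 1e-10)

  # collinear covariates are dropped with a warning
  cv <- cbind(a = g8, b = g8)
  expect_warning(calibrateLinear(ScoreSet(score = g8, trait = y8,
                                          covariates = cv)), "collinear")
})

test_that("decile calibration is conservative and translation-covariant", {
  set.seed(48)
  n <- 200
  pred <- rnorm(n)
  # perfect calibration: all differences zero
  cal <- calibrationByDecile(pred, pred)
  expect_equal(cal$decile_table$difference, rep(0, 10))
  expect_equal(sum(cal$decile_table$n), n)

  obs <- pred + rnorm(n, 0, 0.5)
  cal2 <- calibrationByDecile(pred, obs)
  # decile counts sum to n; weighted mean observed recovers overall mean
  expect_equal(sum(cal2$decile_table$n), n)
  expect_equal(
    sum(cal2$decile_table$mean_observed * cal2$decile_table$n) / n,
    mean(obs), tolerance = 1e-12)
  # adding c to predictions shifts every difference by -c
  cal3 <- calibrationByDecile(pred + 0.7, obs)
  expect_equal(cal3$decile_table$difference,
               cal2$decile_table$difference - 0.7, tolerance = 1e-12)
  expect_error(calibrationByDecile(1:5, 1:5), "at least")
})

test_that("the Hosmer-Lemeshow statistic matches a two-bin hand sum", {
  # hand-specified bins: (O, E, n) = (12, 10, 50) and (30, 34, 60)
  hl <- grabld:::.hosmerLemeshow(obs = c(12, 30), exp = c(10, 34),
                                 ng = c(50, 60))
  byHand <- (12 - 10)^2 / (10 * (1 - 10 / 50)) +
    (30 - 34)^2 / (34 * (1 - 34 / 60))
  expect_equal(hl$statistic, byHand, tolerance = 1e-12)

  # full decile path: 10 bins, chi-squared on 8 df
  set.seed(49)
  n <- 500
  p <- runif(n, 0.1, 0.9)
  yb <- rbinom(n, 1, p)
  cal <- calibrationByDecile(p, yb, binary = TRUE)
  expect_equal(cal$hl_df, 8L)
  expect_equal(cal$hl_pvalue,
               pchisq(cal$hl_statistic, 8, lower.tail = FALSE))
  expect_gte(cal$hl_statistic, 0)

  # degenerate expected counts are merged with a neighbour
  p2 <- c(rep(0, 50), runif(450, 0.2, 0.8))
  y2 <- rbinom(500, 1, p2)
  expect_message(cal2 <- calibrationByDecile(p2, y2, binary = TRUE),
                 "merged")
})

test_that("mean absolute difference is the plain residual mean", {
  y <- rnorm(12)
  expect_equal(meanAbsDifference(y, y), 0)
  expect_equal(meanAbsDifference(y + 1, y), 1)
  p5 <- c(0.1, -0.4, 0.9, 0.2, -0.7)
  o5 <- c(0.3, -0.1, 0.5, 0.2, -1.2)
  expect_equal(meanAbsDifference(p5, o5),
               mean(c(0.2, 0.3, 0.4, 0, 0.5)), tolerance = 1e-12)
})

test_that("evaluateScores assembles a coherent report", {
  set.seed(50)
  n <- 300
  g <- rnorm(n)
  y <- 0.6 * g + rnorm(n, 0, 0.8)
  y <- (y - mean(y)) / sd(y)
  rep1 <- evaluateScores(ScoreSet(score = g, trait = y))
  expect_s4_class(rep1, "EvalReport")
  expect_true(rep1@r2 > 0 && rep1@r2 <= 1)
  expect_true(is.na(rep1@auc))
  expect_equal(nrow(rep1@decileTable), 10L)

  lab <- rbinom(n, 1, plogis(g))
  rep2 <- evaluateScores(ScoreSet(score = g, trait = lab,
                                  traitType = "binary"),
                         predicted = plogis(g))
  expect_true(rep2@auc > 0.5)
  expect_gte(rep2@hlStatistic, 0)
  expect_true(is.na(rep2@r2))

  # reports serialize to JSON
  path <- tempfile(fileext = ".json")
  writeEvalReport(rep2, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$auc, rep2@auc, tolerance = 1e-9)
})
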