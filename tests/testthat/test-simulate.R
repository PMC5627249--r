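test_that("the no-LD model yields essentially uncorrelated SNPs", {
  set.seed(60)
  pool <- generateHaplotypePool(SimConfig(mSnps = 40L, ldModel = "none",
                                          poolSize = 4000L, seed = 60L))
  n <- 4000
  xs <- grabld:::cpp_standardize_cols(drawGenotypes(pool, n))$x
  r <- crossprod(xs) / n
  offDiag <- abs(r[upper.tri(r)])
  expect_gt(mean(offDiag < 4 / sqrt(n)), 0.99)
})

test_that("perfect-LD blocks reproduce the five-duplicate example", {
  set.seed(61)
  pool <- generateHaplotypePool(SimConfig(mSnps = 20L, blockSize = 5L,
                                          withinR2 = 1, blockMix = 1,
                                          poolSize = 500L, seed = 61L))
  x <- drawGenotypes(pool, 200)
  # shared frequency + latent correlation 1: identical columns in a block
  for (b in 1:4) {
    cols <- ((b - 1) * 5 + 1):(b * 5)
    expect_equal(x[, cols], x[, rep(cols[1], 5)], ignore_attr = TRUE)
  }
  xs <- grabld:::cpp_standardize_cols(x)$x
  # within one block (window confined to it) eta is exactly 5
  eta1 <- etaValues(computeEta(xs[, 1:5], window = 4))
  expect_equal(unname(eta1), rep(5, 5), tolerance = 1e-12)
  # across the region, cross-block sampling r2 only nudges eta upward
  eta <- etaValues(computeEta(xs, window = 4))
  expect_true(all(eta >= 5 - 1e-12 & eta < 5.25))
})

test_that("realized within-block r2 concentrates on its target", {
  set.seed(62)
  pool <- generateHaplotypePool(SimConfig(mSnps = 100L, blockSize = 10L,
                                          withinR2 = 0.5, blockMix = 1,
                                          poolSize = 4000L, seed = 62L))
  n <- 5000
  xs <- grabld:::cpp_standardize_cols(drawGenotypes(pool, n))$x
  r <- crossprod(xs) / n
  within <- numeric(0)
  for (b in 1:10) {
    cols <- ((b - 1) * 10 + 1):(b * 10)
    rb <- r[cols, cols]
    within <- c(within, rb[upper.tri(rb)]^2)
  }
  expect_lt(abs(mean(within) - 0.5), 0.1)
})

test_that("the mixed-block default model spans its r2 levels", {
  set.seed(63)
  cfg <- SimConfig(mSnps = 90L, poolSize = 3000L, seed = 63L)
  pool <- generateHaplotypePool(cfg)
  expect_equal(sort(unique(pool@targetR2)), c(0.2, 0.5, 0.8))
  counts <- table(pool@targetR2[seq(1, 90, by = 5)])
  expect_equal(unname(counts["0.8"]) / 18, 0.7, tolerance = 0.1)
  n <- 4000
  xs <- grabld:::cpp_standardize_cols(drawGenotypes(pool, n))$x
  r <- crossprod(xs) / n
  for (lev in c(0.2, 0.5, 0.8)) {
    blocks <- unique(pool@blockId[pool@targetR2 == lev])
    within <- numeric(0)
    for (b in blocks) {
      cols <- which(pool@blockId == b)
      rb <- r[cols, cols]
      within <- c(within, rb[upper.tri(rb)]^2)
    }
    expect_lt(abs(mean(within) - lev), 0.1)
  }
})

test_that("the mosaic model produces distance-decaying LD", {
  set.seed(64)
  pool <- generateHaplotypePool(SimConfig(mSnps = 60L, ldModel = "mosaic",
                                          switchRate = 0.05,
                                          poolSize = 1000L, seed = 64L))
  xs <- grabld:::cpp_standardize_cols(drawGenotypes(pool, 2000))$x
  r2 <- (crossprod(xs) / 2000)^2
  adj <- mean(r2[cbind(1:59, 2:60)])
  far <- mean(r2[cbind(1:30, 31:60)])
  # template sharing induces LD that decays with distance
  expect_gt(adj, 2 * far)
  expect_gt(adj, 0.01)
})

test_that("simulated effects follow the Normal(0, h2/m) law", {
  expect_equal(simulateEffects(25, 0), rep(0, 25))
  set.seed(65)
  b <- as.vector(replicate(1000, simulateEffects(450, 0.5)))
  s2 <- var(b)
  se <- (0.5 / 450) * sqrt(2 / (length(b) - 1))
  expect_lt(abs(s2 - 0.5 / 450), 3 * se)
  # quadrupling h2 doubles the effect SD draw-for-draw
  set.seed(66); b1 <- simulateEffects(100, 0.1)
  set.seed(66); b2 <- simulateEffects(100, 0.4)
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
})

test_that("simulated traits have unit variance and exact noiseless limit", {
  xs <- stdMatrix(5000, 450, seed = 67)
  set.seed(67)
  # h2 = 0: pure noise with variance 1
  y0 <- simulateTrait(xs, rep(0, 450), 0)
  expect_lt(abs(var(y0) - 1), 0.05)
  # moderate h2 at the default SNP count: total variance near 1
  beta <- simulateEffects(450, 0.5)
  y <- simulateTrait(xs, beta, 0.5)
  expect_lt(abs(var(y) - 1), 0.05)
  # noiseless edge: y = X beta exactly
  y1 <- simulateTrait(xs, beta, 1)
  expect_equal(y1, drop(xs %*% beta), tolerance = 1e-12)
  expect_error(simulateTrait(xs, beta, 1.2), "exceeds 1")
})

test_that("external coefficients estimate LD-projected effects", {
  set.seed(68)
  # no LD, large N: b* converges to beta elementwise
  poolI <- generateHaplotypePool(SimConfig(mSnps = 30L, ldModel = "none",
                                           poolSize = 4000L, seed = 68L))
  beta <- simulateEffects(30, 0.3)
  ext <- simulateExternalStudy(poolI, 40000L, beta, 0.3)
  expect_true(all(abs(ext$b_star - beta) < 4 / sqrt(40000)))

  # null effects: mean near 0, per-SNP variance near 1/N
  set.seed(69)
  b0 <- replicate(60, simulateExternalStudy(poolI, 800L, rep(0, 30),
                                            0)$b_star)
  expect_lt(abs(mean(b0)), 0.005)
  expect_lt(abs(var(as.vector(b0)) - 1 / 800), 0.3 / 800)

  # perfect-LD block: every b* estimates the block's summed effect
  set.seed(70)
  poolB <- generateHaplotypePool(SimConfig(mSnps = 10L, blockSize = 5L,
                                           withinR2 = 1, blockMix = 1,
                                           poolSize = 1000L, seed = 70L))
  betaB <- simulateEffects(10, 0.3)
  extB <- simulateExternalStudy(poolB, 30000L, betaB, 0.3)
  blockSums <- rep(c(sum(betaB[1:5]), sum(betaB[6:10])), each = 5)
  expect_true(all(abs(extB$b_star - blockSums) < 4 / sqrt(30000) + 0.01))
})

test_that("the raw-moment external path equals explicit standardization", {
  set.seed(71)
  pool <- generateHaplotypePool(SimConfig(mSnps = 25L, poolSize = 300L,
                                          seed = 71L))
  beta <- simulateEffects(25, 0.4)
  set.seed(72)
  ext <- simulateExternalStudy(pool, 400L, beta, 0.4)
  set.seed(72)
  H <- ncol(pool@haplotypes)
  x <- t(grabld:::cpp_draw_t(pool@haplotypes,
                             sample.int(H, 400, TRUE),
                             sample.int(H, 400, TRUE)))
  xs <- grabld:::cpp_standardize_cols(x)$x
  y <- drop(xs %*% beta) + rnorm(400, 0, sqrt(0.6))
  y <- y - mean(y)
  expect_equal(ext$b_star, drop(crossprod(xs, y)) / 400, tolerance = 1e-12)
})

test_that("theory experiments are seed-deterministic", {
  cfg <- SimConfig(nTarget = 300L, nExternal = 600L, mSnps = 30L,
                   h2Grid = c(0.1, 0.4), nReps = 5L, poolSize = 400L,
                   seed = 99L)
  a <- runTheoryExperiment(cfg)
  b <- runTheoryExperiment(cfg)
  expect_identical(a@replicates, b@replicates)
  cfg2 <- SimConfig(nTarget = 300L, nExternal = 600L, mSnps = 30L,
                    h2Grid = c(0.1, 0.4), nReps = 5L, poolSize = 400L,
                    seed = 100L)
  c <- runTheoryExperiment(cfg2)
  expect_false(identical(a@replicates, c@replicates))
  # replicate table has the documented shape
  expect_equal(nrow(a@replicates), 10L)
  expect_true(all(a@replicates$var_g >= 0))
  expect_true(all(a@replicates$pred_r2 >= 0 & a@replicates$pred_r2 <= 1))
})

test_that("a zero-heritability set-point gives null covariance", {
  res <- runTheoryExperiment(SimConfig(nTarget = 500L, nExternal = 1000L,
                                       mSnps = 30L, h2Grid = 0,
                                       nReps = 30L, poolSize = 500L,
                                       seed = 101L))
  s <- res@summary
  expect_equal(s$mean_r2_true, 0)
  expect_lt(abs(s$mean_cov_gy), 3 * s$se_cov_gy + 1e-8)
  expect_true(is.na(s$recovery_ratio))
})

test_that("the end-to-end recovery experiment is structured and reproducible", {
  cfg <- SimConfig(nTarget = 600L, nExternal = 3000L, mSnps = 60L,
                   h2Grid = 0.5, nReps = 3L, poolSize = 1000L, seed = 77L)
  bc <- BoostConfig(nTrees = 100L, seed = 5L)
  out <- runEndToEndRecovery(cfg, bc, inflation = 2)
  expect_equal(nrow(out), 3L)
  expect_true(all(out$r2_grabld >= 0 & out$r2_grabld <= 1))
  expect_true(all(out$r2_oracle >= 0 & out$r2_oracle <= 1))
  out2 <- runEndToEndRecovery(cfg, bc, inflation = 2)
  expect_identical(out, out2)
  # undistorted control: with nothing to adapt, tuning tracks the
  # unadjusted score to within Monte-Carlo error
  ctrl <- runEndToEndRecovery(cfg, bc, inflation = 1)
  expect_lt(mean(abs(ctrl$r2_grabld - ctrl$r2_unadjusted)), 0.05)
})

test_that("fixture cohorts harmonize and score end to end", {
  dir <- tempfile("cohort")
  paths <- writeFixtureCohort(dir, SimConfig(nTarget = 150L, mSnps = 40L,
                                             nExternal = 2000L,
                                             poolSize = 400L, seed = 102L),
                              h2 = 0.5)
  stats <- readSummaryStats(paths$sumstats)
  panel <- readGenotypes(paths$bed)
  ph <- readPhenotypeTable(paths$pheno)
  study <- harmonizeStudy(panel, stats,
                          phenotype = setNames(ph$phenotype, rownames(ph)),
                          verbose = FALSE)
  expect_equal(nrow(study), 40L)
  wt <- boostWeights(study, BoostConfig(nTrees = 50L, seed = 1L))
  wt <- ldAdjustWeights(wt, study, window = 10L)
  ss <- computeScore(study, wt)
  expect_equal(length(scores(ss)), 150L)
  expect_gt(evaluateR2(ss)$r2, 0)
})
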