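## Latent-Gaussian threshold correlation: haplotype alleles within a block
## are thresholded correlated normals.  Thresholding attenuates correlation,
## so the latent correlation is solved (per block) such that the *realized*
## binary correlation equals the requested value.
.solveLatentRho <- function(rho, p) {
  if (rho >= 0.999) return(1)
  if (rho <= 0) return(0)
  t <- qnorm(p)
  f <- function(rz) {
    pr <- mvtnorm::pmvnorm(upper = c(t, t),
                           corr = matrix(c(1, rz, rz, 1), 2))[1]
    (pr - p^2) / (p * (1 - p)) - rho
  }
  uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

#' Generate a synthetic haplotype pool
#'
#' Builds a founder pool of binary haplotypes on one synthetic chromosome.
#' Three LD models are available.  `none`: every SNP independent with allele
#' frequency uniform on \[0.05, 0.95\].  `blocks` (default): SNPs come in
#' blocks of `blockSize`; within a block all SNPs share one allele frequency
#' and are generated from a latent equicorrelated Gaussian whose correlation
#' is solved so the realized genotype r-squared concentrates on the block's
#' target level; blocks are independent of each other, and target levels are
#' assigned across blocks according to `withinR2`/`blockMix`.  `mosaic`:
#' haplotypes are segmental copies of a small founder set with geometric
#' switch points at rate `switchRate` per SNP.
#'
#' Diploid cohorts are drawn from the pool by random mating
#' ([drawGenotypes()]), so the pool plays the role of the source population.
#'
#' @param config a [SimConfig-class].
#'
#' @return A [HaplotypePool-class].
#' @export
generateHaplotypePool <- function(config) {
  stopifnot(is(config, "SimConfig"))
  H <- config@poolSize
  m <- config@mSnps
  hap <- matrix(0, H, m)
  blockId <- integer(m)
  targetR2 <- numeric(m)
  freq <- numeric(m)
  if (config@ldModel == "none") {
    freq <- runif(m, 0.05, 0.95)
    hap <- matrix(rbinom(H * m, 1, rep(freq, each = H)), H, m)
    blockId <- seq_len(m)
  } else if (config@ldModel == "blocks") {
    B <- config@blockSize
    nBlocks <- ceiling(m / B)
    counts <- .allocateBlocks(nBlocks, config@blockMix)
    levels <- rep(config@withinR2, counts)
    for (b in seq_len(nBlocks)) {
      cols <- (((b - 1) * B + 1):min(b * B, m))
      p <- runif(1, 0.05, 0.95)
      r2 <- levels[b]
      rho <- sqrt(r2)
      rz <- .solveLatentRho(rho, p)
      k <- length(cols)
      if (rz >= 1) {
        z <- matrix(rnorm(H), H, k)
      } else {
        S <- matrix(rz, k, k); diag(S) <- 1
        z <- mvtnorm::rmvnorm(H, sigma = S)
      }
      hap[, cols] <- (z < qnorm(p)) + 0
      blockId[cols] <- b
      targetR2[cols] <- r2
      freq[cols] <- p
    }
  } else {  # mosaic
    nFounders <- 20L
    freq <- runif(m, 0.05, 0.95)
    founders <- matrix(rbinom(nFounders * m, 1, rep(freq, each = nFounders)),
                       nFounders, m)
    switches <- matrix(runif(H * m) < config@switchRate, H, m)
    switches[, 1] <- TRUE
    for (i in seq_len(H)) {
      sw <- which(switches[i, ])
      tpl <- sample.int(nFounders, length(sw), replace = TRUE)
      seg <- rep(tpl, times = diff(c(sw, m + 1L)))
      hap[i, ] <- founders[cbind(seg, seq_len(m))]
    }
    blockId <- seq_len(m)
  }
  ## guard against SNPs fixed in the finite pool
  mono <- which(colSums(hap) %in% c(0L, nrow(hap)))
  for (j in mono) hap[sample.int(H, 2L), j] <- 1 - hap[1L, j]
  new("HaplotypePool", haplotypes = t(hap), chrom = rep("1", m),
      pos = seq_len(m) * 1000L, blockId = blockId, targetR2 = targetR2,
      freq = freq, ldModel = config@ldModel)
}

## Largest-remainder allocation of nBlocks across mixture fractions.
.allocateBlocks <- function(nBlocks, mix) {
  raw <- nBlocks * mix
  counts <- floor(raw)
  rem <- nBlocks - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Draw a diploid cohort from a haplotype pool
#'
#' Random mating: each individual is the sum of two haplotypes drawn with
#' replacement from the pool.
#'
#' @param pool a [HaplotypePool-class].
#' @param n number of individuals.
#'
#' @return n x m dosage matrix (entries 0/1/2).
#' @export
drawGenotypes <- function(pool, n) {
  H <- ncol(pool@haplotypes)
  t(cpp_draw_t(pool@haplotypes,
               sample.int(H, n, replace = TRUE),
               sample.int(H, n, replace = TRUE)))
}

## Draw a cohort and standardize per SNP in one fused pass, keeping the
## SNP-major (m x n) layout used by the experiment loops.
.drawStdT <- function(pool, n) {
  H <- ncol(pool@haplotypes)
  cpp_draw_std_t(pool@haplotypes,
                 sample.int(H, n, replace = TRUE),
                 sample.int(H, n, replace = TRUE))
}

#' Simulate true per-SNP genetic effects
#'
#' Effects are i.i.d. Normal(0, h2/m) on the standardized-genotype scale, so
#' the total expected genetic variance of the region is `m * (h2/m) = h2`.
#'
#' @param m SNP count.
#' @param h2 true regional genetic variance in \[0, 1\].
#'
#' @return Numeric effect vector (identically 0 when `h2 = 0`).
#' @export
simulateEffects <- function(m, h2) {
  stopifnot(h2 >= 0, h2 <= 1)
  if (h2 == 0) return(numeric(m))
  rnorm(m, 0, sqrt(h2 / m))
}

#' Simulate an additive quantitative trait
#'
#' `y = X beta + e` with `e ~ Normal(0, 1 - h2)` i.i.d., so the trait has
#' expected variance 1.
#'
#' @param xStd samples-by-SNPs standardized genotype matrix.
#' @param beta effect vector on the standardized scale.
#' @param h2 the genetic variance `m * sigma^2` implied by `beta`'s
#'   distribution; must not exceed 1.
#'
#' @return Numeric trait vector.
#' @export
simulateTrait <- function(xStd, beta, h2) {
  if (h2 > 1) stop("genetic variance exceeds 1; no room for noise")
  drop(xStd %*% beta) + rnorm(nrow(xStd), 0, sqrt(1 - h2))
}

#' Simulate an external summary-statistic study
#'
#' Draws an independent cohort of `nExternal` individuals from the pool,
#' simulates its trait under the same effects, and returns the univariate
#' summary coefficients `b*_j = x*_j' y* / N` computed on standardized
#' external genotype columns (the estimator consortium meta-analyses
#' report).
#'
#' @param pool a [HaplotypePool-class].
#' @param nExternal external sample size N.
#' @param beta true effect vector.
#' @param h2 true regional genetic variance.
#'
#' @return List with `b_star` (length-m coefficients) and `n_external`.
#' @export
simulateExternalStudy <- function(pool, nExternal, beta, h2) {
  ## raw dosages + moments; the standardization is folded in algebraically:
  ## with x_j = (raw_j - mu_j)/s_j and centered y*, x_j' y* = raw_j' y* / s_j
  H <- ncol(pool@haplotypes)
  raw <- cpp_draw_moments_t(pool@haplotypes,
                            sample.int(H, nExternal, replace = TRUE),
                            sample.int(H, nExternal, replace = TRUE))
  s <- ifelse(raw$sd > 0, raw$sd, 1)
  bs <- beta / s
  y <- drop(crossprod(raw$x, bs)) - sum(raw$mean * bs) +
    rnorm(nExternal, 0, sqrt(1 - h2))
  y <- y - mean(y)
  list(b_star = drop(raw$x %*% y) / (nExternal * s),
       n_external = nExternal)
}

#' Emit a simulated cohort as PLINK + TSV fixtures
#'
#' Writes a drawn cohort as PLINK BED/BIM/FAM, a phenotype TSV and an
#' external summary-statistic TSV, so the I/O and harmonization modules can
#' be exercised offline on synthetic data.  Alleles are coded A (counted,
#' dosage allele) / G.
#'
#' @param dir output directory (created if needed).
#' @param config a [SimConfig-class]; `nTarget`, `mSnps`, the LD model and
#'   `seed` are honoured.
#' @param h2 genetic variance for the simulated trait.
#'
#' @return Invisible list of written paths (`bed`, `pheno`, `sumstats`).
#' @export
writeFixtureCohort <- function(dir, config = SimConfig(nTarget = 200L,
                                                       mSnps = 50L,
                                                       poolSize = 400L),
                               h2 = 0.3) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config@seed)
  pool <- generateHaplotypePool(config)
  m <- config@mSnps
  x <- drawGenotypes(pool, config@nTarget)
  std <- cpp_standardize_cols(x)
  keep <- which(std$sd > 0)
  beta <- simulateEffects(m, h2)
  y <- simulateTrait(std$x[, keep, drop = FALSE], beta[keep], h2)
  ext <- simulateExternalStudy(pool, max(config@nExternal, 1000L), beta, h2)

  ids <- sprintf("sim%04d", seq_len(config@nTarget))
  snps <- sprintf("rs%05d", seq_len(m))
  variants <- data.frame(snp_id = snps, chrom = pool@chrom, pos = pool@pos,
                         allele1 = "A", allele2 = "G",
                         stringsAsFactors = FALSE)
  panel <- GenotypePanel(t(x), variants, ids)
  prefix <- file.path(dir, "cohort")
  writePlink(panel, prefix)

  phenoPath <- file.path(dir, "phenotype.tsv")
  utils::write.table(data.frame(sample_id = ids, phenotype = y),
                     phenoPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ssPath <- file.path(dir, "sumstats.tsv")
  utils::write.table(data.frame(MarkerName = snps, chr = pool@chrom,
                                pos = pool@pos, Allele1 = "A",
                                Allele2 = "G", b = ext$b_star,
                                Freq.Allele1.HapMapCEU = pool@freq,
                                N = ext$n_external),
                     ssPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(bed = paste0(prefix, ".bed"), pheno = phenoPath,
                 sumstats = ssPath))
}
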