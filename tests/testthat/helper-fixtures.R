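# Shared fixtures and independent oracles.  All fixtures are built in code.

# Random matrix with columns standardized to mean 0, population variance 1.
stdMatrix <- function(n, m, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * m), n, m)
  mu <- colMeans(x)
  s <- sqrt(colMeans(x^2) - mu^2)
  sweep(sweep(x, 2, mu), 2, s, "/")
}

# Small harmonized study built from explicit pieces.
tinyStudy <- function(n = 50, m = 12, h2 = 0.4, seed = 1) {
  set.seed(seed)
  x <- matrix(rbinom(n * m, 2, 0.4), n, m)
  while (any(apply(x, 2, var) == 0))
    x <- matrix(rbinom(n * m, 2, 0.4), n, m)
  beta <- rnorm(m, 0, sqrt(h2 / m))
  xs <- grabld:::cpp_standardize_cols(x)$x
  y <- drop(xs %*% beta) + rnorm(n, 0, sqrt(1 - h2))
  makeHarmonizedStudy(x, beta, phenotype = y)
}

# O(m^2 n) brute-force windowed sum of squared Pearson correlations.
bruteForceEta <- function(x, window, chrom = rep("1", ncol(x))) {
  m <- ncol(x)
  eta <- numeric(m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (chrom[j] == chrom[k] && abs(j - k) <= window)
        eta[j] <- eta[j] + cor(x[, j], x[, k])^2
    }
  }
  eta
}

# Exhaustive case/control pair counting AUC (ties count one half).
allPairsAUC <- function(score, label) {
  cases <- score[label == 1]
  controls <- score[label == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Summary-statistic TSV in the consortium dialect.
writeSumstatsTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# A small deterministic genotype panel with explicit alleles.
tinyPanel <- function(dosage, alleles, chrom = NULL, pos = NULL) {
  m <- nrow(dosage)
  variants <- data.frame(
    snp_id = paste0("rs", seq_len(m)),
    chrom = if (is.null(chrom)) rep("1", m) else chrom,
    pos = if (is.null(pos)) seq_len(m) * 100L else pos,
    allele1 = alleles[, 1], allele2 = alleles[, 2],
    stringsAsFactors = FALSE)
  GenotypePanel(dosage, variants, paste0("s", seq_len(ncol(dosage))))
}
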