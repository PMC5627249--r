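#' Windowed sum-of-r2 LD adjustment
#'
#' For each score SNP j, computes `eta_j`, the sum of squared Pearson
#' correlations between SNP j and every score SNP within `window` SNPs on
#' either side on the same chromosome (the self term contributes 1, so an
#' isolated SNP has `eta = 1`).  Only SNPs included in the score should be
#' present in `x`: the adjustment is specific to the scored SNP set.
#' Windows are truncated at chromosome ends and never cross chromosomes.
#'
#' @param x a [HarmonizedStudy-class], or a samples-by-SNPs genotype matrix
#'   with standardized columns in genome order.
#' @param window positive integer SNP-count radius (default 100).
#' @param chrom optional per-SNP chromosome labels (matrix input only;
#'   a single chromosome is assumed when omitted).
#' @param r2Floor squared correlations strictly below this value are zeroed
#'   before summation (default 0: the literal formula).
#'
#' @return An [EtaVector-class].
#' @export
computeEta <- function(x, window = 100L, chrom = NULL, r2Floor = 0) {
  if (window < 1) stop("window must be a positive integer")
  window <- as.integer(window)
  if (is(x, "HarmonizedStudy")) {
    chrom <- snpInfo(x)$chrom
    ids <- snpInfo(x)$snp_id
    x <- genotypeMatrix(x)
  } else {
    x <- as.matrix(x)
    ids <- colnames(x)
  }
  m <- ncol(x)
  if (is.null(chrom)) chrom <- rep("1", m)
  stopifnot(length(chrom) == m)
  x <- cpp_standardize_cols(x)$x  # idempotent on standardized input
  eta <- .etaFromStd(x, window, chrom, r2Floor)
  if (!is.null(ids)) names(eta) <- ids
  new("EtaVector", eta = eta, window = window)
}

## As .etaFromStd, but on a SNP-major (m x n) standardized matrix, the
## layout the simulation loops use.
.etaFromStdT <- function(xT, window, chrom, r2Floor = 0) {
  m <- nrow(xT)
  if (m > 1500L) return(.etaFromStd(t(xT), window, chrom, r2Floor))
  n <- ncol(xT)
  eta <- numeric(m)
  for (ch in unique(chrom)) {
    rows <- which(chrom == ch)
    r2 <- (tcrossprod(xT[rows, , drop = FALSE]) / n)^2
    if (r2Floor > 0) r2[r2 < r2Floor & row(r2) != col(r2)] <- 0
    mc <- length(rows)
    for (j in seq_len(mc)) {
      k <- max(1L, j - window):min(mc, j + window)
      eta[rows[j]] <- sum(r2[j, k])
    }
  }
  eta
}

## Banded sum of squared correlations on an already-standardized matrix.
.etaFromStd <- function(x, window, chrom, r2Floor = 0) {
  m <- ncol(x)
  n <- nrow(x)
  eta <- numeric(m)
  for (ch in unique(chrom)) {
    cols <- which(chrom == ch)
    mc <- length(cols)
    xc <- x[, cols, drop = FALSE]
    if (mc <= 1500L) {
      r2 <- (crossprod(xc) / n)^2
      if (r2Floor > 0) r2[r2 < r2Floor & row(r2) != col(r2)] <- 0
      for (j in seq_len(mc)) {
        k <- max(1L, j - window):min(mc, j + window)
        eta[cols[j]] <- sum(r2[j, k])
      }
    } else {
      chunk <- 512L
      for (a in seq(1L, mc, by = chunk)) {
        b <- min(mc, a + chunk - 1L)
        lo <- max(1L, a - window); hi <- min(mc, b + window)
        r2 <- (crossprod(xc[, a:b, drop = FALSE],
                         xc[, lo:hi, drop = FALSE]) / n)^2
        for (j in a:b) {
          k <- (max(lo, j - window):min(hi, j + window)) - lo + 1L
          row <- j - a + 1L
          v <- r2[row, k]
          if (r2Floor > 0) {
            self <- j - max(lo, j - window) + 1L
            v[-self][v[-self] < r2Floor] <- 0
          }
          eta[cols[j]] <- sum(v)
        }
      }
    }
  }
  eta
}

#' Divide weights by the LD adjustment
#'
#' Applies the elementwise correction `w_tilde_j = w_j / eta_j`, so that a
#' group of SNPs in perfect mutual LD jointly contributes to the score like
#' a single uncorrected SNP.
#'
#' @param weights length-m numeric vector of (boosted) weights.
#' @param eta an [EtaVector-class] or numeric vector aligned to `weights`.
#'
#' @return Numeric vector of LD-corrected weights.
#' @export
applyLDCorrection <- function(weights, eta) {
  e <- if (is(eta, "EtaVector")) etaValues(eta) else as.numeric(eta)
  if (length(weights) != length(e))
    stop("weights (", length(weights), ") and eta (", length(e),
         ") lengths differ")
  weights / e
}

#' Write / read a weight table as TSV
#'
#' @param wt a [WeightTable-class].
#' @param path output/input path.
#'
#' @return `writeWeightTable` returns `path` invisibly; `readWeightTable`
#'   returns a [WeightTable-class].
#' @export
writeWeightTable <- function(wt, path) {
  utils::write.table(as.data.frame(wt), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeWeightTable
#' @export
readWeightTable <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  new("WeightTable", S4Vectors::DataFrame(df))
}
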