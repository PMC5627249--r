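.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(a1, a2) {
  ok <- a1 %in% names(.COMPLEMENT) & a2 %in% names(.COMPLEMENT)
  ok & unname(.COMPLEMENT[a1]) == a2
}

## Resolve summary (EA, OA) against panel (a1 coded, a2), returning +1
## (aligned), -1 (effect allele is the panel's other allele) or NA
## (irresolvable). Palindromic SNPs are left to the caller's policy.
.alleleSign <- function(ea, oa, a1, a2) {
  cea <- unname(.COMPLEMENT[ea])
  coa <- unname(.COMPLEMENT[oa])
  s <- rep(NA_real_, length(ea))
  s[ea == a1 & oa == a2] <- 1
  s[is.na(s) & ea == a2 & oa == a1] <- -1
  s[is.na(s) & cea == a1 & coa == a2] <- 1
  s[is.na(s) & cea == a2 & coa == a1] <- -1
  s
}

#' Standardize genotype dosages
#'
#' Replaces missing entries by the per-SNP mean, then centers and scales
#' every SNP to mean 0 and population variance 1 (divide by n).  Monomorphic
#' SNPs are removed and reported.
#'
#' @param panel a [GenotypePanel-class], or a samples-by-SNPs dosage matrix.
#' @param verbose print the removal count.
#'
#' @return A list with `genotypes` (samples x SNPs standardized matrix),
#'   `removed` (character ids or column indices of monomorphic SNPs),
#'   `mean` and `sd` (per retained SNP, on the imputed dosages).
#' @export
standardizeGenotypes <- function(panel, verbose = TRUE) {
  x <- if (is(panel, "GenotypePanel")) genotypeMatrix(panel) else
    as.matrix(panel)
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x))
    x[idx] <- mu[(idx - 1) %/% nrow(x) + 1]
  }
  std <- cpp_standardize_cols(x)
  mono <- which(std$sd == 0 | is.na(std$sd))
  if (length(mono) == ncol(x))
    stop("all SNPs are monomorphic; nothing to standardize")
  if (length(mono) && verbose)
    message("standardizeGenotypes: removed ", length(mono),
            " monomorphic SNP(s)")
  g <- std$x
  dimnames(g) <- dimnames(x)
  removed <- if (is.null(colnames(x))) mono else colnames(x)[mono]
  if (length(mono)) g <- g[, -mono, drop = FALSE]
  list(genotypes = g,
       removed = removed,
       mean = drop(std$mean)[setdiff(seq_len(ncol(x)), mono)],
       sd = drop(std$sd)[setdiff(seq_len(ncol(x)), mono)])
}

#' Harmonize a genotype panel with external summary statistics
#'
#' Intersects panel variants with the summary table, aligns the external
#' effect sizes to the panel's coded allele (flipping signs where the coded
#' allele is the summary's other allele, resolving strand flips via allele
#' complements, and handling palindromic A/T and C/G SNPs per policy),
#' standardizes the genotypes, and attaches the phenotype and covariates.
#'
#' @param panel a [GenotypePanel-class].
#' @param stats a [SummaryStats-class] on the per-SD scale.
#' @param phenotype optional numeric vector, named by sample id (unnamed
#'   vectors must match the panel's sample order).  0/1 vectors are treated
#'   as binary labels; anything else is standardized to mean 0, population
#'   variance 1.
#' @param covariates optional matrix/data.frame of covariates, rows matching
#'   the panel samples (by rowname when present).
#' @param matchBy `"id"` (rsID key) or `"position"` (`chrom:pos` key).
#' @param palindromic `"drop"` (default) or `"freq"`: frequency-based
#'   resolution, used only when both panel and summary frequencies are at
#'   least `freqThreshold` away from 0.5.
#' @param freqThreshold minimum |frequency - 0.5| for `"freq"` resolution.
#' @param residualize when `TRUE`, a quantitative phenotype is replaced by
#'   its residual on the covariates before standardization.
#' @param trim when `TRUE`, samples outside the 1st-99th percentile of a
#'   quantitative phenotype are removed.
#' @param verbose print drop counts.
#'
#' @return A [HarmonizedStudy-class] with SNPs in genome order.
#' @export
harmonizeStudy <- function(panel, stats, phenotype = NULL, covariates = NULL,
                           matchBy = c("id", "position"),
                           palindromic = c("drop", "freq"),
                           freqThreshold = 0.08, residualize = FALSE,
                           trim = FALSE, verbose = TRUE) {
  matchBy <- match.arg(matchBy)
  palindromic <- match.arg(palindromic)
  info <- snpInfo(panel)
  key <- function(id, chrom, pos)
    if (matchBy == "id") as.character(id) else paste0(chrom, ":", pos)
  pk <- key(info$snp_id, info$chrom, info$pos)
  sk <- key(stats$snp_id, stats$chrom, stats$pos)
  hit <- match(pk, sk)
  if (all(is.na(hit)))
    stop("no overlapping SNPs between panel and summary statistics")

  idx <- which(!is.na(hit))
  st <- stats[hit[idx], , drop = FALSE]
  a1 <- info$allele1[idx]; a2 <- info$allele2[idx]
  ea <- st$effect_allele; oa <- st$other_allele
  sgn <- .alleleSign(ea, oa, a1, a2)
  pal <- .isPalindromic(a1, a2)

  if (palindromic == "drop") {
    sgn[pal] <- NA
  } else {
    dosage <- SummarizedExperiment::assay(panel, "dosage")
    paf <- rowMeans(dosage, na.rm = TRUE)[idx] / 2  # coded-allele frequency
    eaf <- if ("eaf" %in% colnames(st)) st$eaf else rep(NA_real_, nrow(st))
    usable <- pal & !is.na(sgn) & !is.na(eaf) &
      abs(eaf - 0.5) > freqThreshold & abs(paf - 0.5) > freqThreshold
    sgn[pal & !usable] <- NA
    flip <- usable & ((eaf > 0.5) != (ifelse(sgn < 0, 1 - paf, paf) > 0.5))
    sgn[flip] <- -sgn[flip]
  }
  if (verbose && any(is.na(sgn)))
    message("harmonizeStudy: dropped ", sum(is.na(sgn)),
            " SNP(s) with unresolvable or palindromic alleles")
  keep <- which(!is.na(sgn))
  if (!length(keep))
    stop("no overlapping SNPs remain after allele resolution")
  idx <- idx[keep]; st <- st[keep, , drop = FALSE]; sgn <- sgn[keep]

  sub <- panel[idx, ]
  std <- standardizeGenotypes(sub, verbose = verbose)
  kept <- setdiff(seq_along(idx),
                  match(std$removed, snpInfo(sub)$snp_id))
  info2 <- snpInfo(sub)[kept, , drop = FALSE]
  beta <- st$beta_ext[kept] * sgn[kept]

  g <- t(std$genotypes)  # m x n, standardized rows
  rd <- S4Vectors::DataFrame(snp_id = info2$snp_id, chrom = info2$chrom,
                             pos = info2$pos, allele1 = info2$allele1,
                             allele2 = info2$allele2, beta_ext = beta,
                             row.names = info2$snp_id)
  sampleIds <- colnames(SummarizedExperiment::assay(panel, "dosage"))

  ## phenotype / covariates
  cd <- S4Vectors::DataFrame(row.names = sampleIds)
  covNames <- character()
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    if (!is.null(rownames(cm)) && all(sampleIds %in% rownames(cm)))
      cm <- cm[sampleIds, , drop = FALSE]
    stopifnot(nrow(cm) == length(sampleIds))
    covNames <- colnames(cm)
    if (is.null(covNames)) covNames <- paste0("cov", seq_len(ncol(cm)))
    for (k in seq_along(covNames)) cd[[covNames[k]]] <- cm[, k]
  }
  phenoType <- "none"
  keepSamples <- seq_along(sampleIds)
  if (!is.null(phenotype)) {
    ph <- phenotype
    if (!is.null(names(ph)) && all(sampleIds %in% names(ph)))
      ph <- ph[sampleIds]
    stopifnot(length(ph) == length(sampleIds))
    ph <- as.numeric(ph)
    if (all(ph %in% c(0, 1, NA))) {
      phenoType <- "binary"
    } else {
      phenoType <- "quantitative"
      if (trim) {
        q <- quantile(ph, c(0.01, 0.99), na.rm = TRUE)
        keepSamples <- which(!is.na(ph) & ph >= q[1] & ph <= q[2])
      }
    }
    cd$phenotype <- ph
  }
  if (length(keepSamples) < length(sampleIds)) {
    g <- g[, keepSamples, drop = FALSE]
    cd <- cd[keepSamples, , drop = FALSE]
    restd <- cpp_standardize_cols(t(g))
    g <- t(restd$x)
    if (verbose)
      message("harmonizeStudy: trimmed ",
              length(sampleIds) - length(keepSamples),
              " sample(s) outside the 1st-99th phenotype percentiles")
  }
  if (phenoType == "quantitative") {
    ph <- cd$phenotype
    if (residualize && length(covNames)) {
      cm <- as.matrix(as.data.frame(cd[, covNames, drop = FALSE]))
      ph <- residuals(lm(ph ~ cm))
    }
    ph <- ph - mean(ph)
    cd$phenotype <- ph / sqrt(mean(ph^2))
  }

  o <- order(rd$chrom, rd$pos)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotypes = g[o, , drop = FALSE]),
    rowData = rd[o, , drop = FALSE], colData = cd)
  new("HarmonizedStudy", se, phenotypeType = phenoType,
      covariateNames = covNames)
}

#' Assemble a HarmonizedStudy from aligned pieces
#'
#' Low-level constructor for callers (simulations, tests) that already hold
#' an aligned standardized genotype matrix and effect vector.
#'
#' @param genotypes samples x SNPs matrix, columns standardized to mean 0,
#'   population variance 1 (restandardized here if not).
#' @param beta_ext length-m external effects aligned to the columns.
#' @param phenotype optional numeric vector (0/1 treated as binary;
#'   quantitative values standardized).
#' @param covariates optional covariate matrix.
#' @param chrom,pos optional per-SNP coordinates (defaults: one chromosome,
#'   consecutive positions).
#' @param snp_id,sample_ids optional identifiers.
#'
#' @return A [HarmonizedStudy-class].
#' @export
makeHarmonizedStudy <- function(genotypes, beta_ext, phenotype = NULL,
                                covariates = NULL, chrom = NULL, pos = NULL,
                                snp_id = NULL, sample_ids = NULL) {
  x <- as.matrix(genotypes)
  m <- ncol(x)
  stopifnot(length(beta_ext) == m)
  std <- cpp_standardize_cols(x)
  if (any(std$sd == 0)) stop("monomorphic column(s) in genotypes")
  x <- std$x
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(m))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(x)))
  rd <- S4Vectors::DataFrame(snp_id = snp_id, chrom = as.character(chrom),
                             pos = as.integer(pos),
                             allele1 = rep("A", m), allele2 = rep("G", m),
                             beta_ext = as.numeric(beta_ext),
                             row.names = snp_id)
  cd <- S4Vectors::DataFrame(row.names = sample_ids)
  covNames <- character()
  if (!is.null(covariates)) {
    cm <- as.matrix(as.data.frame(covariates))
    covNames <- colnames(cm)
    if (is.null(covNames)) covNames <- paste0("cov", seq_len(ncol(cm)))
    for (k in seq_along(covNames)) cd[[covNames[k]]] <- cm[, k]
  }
  phenoType <- "none"
  if (!is.null(phenotype)) {
    ph <- as.numeric(phenotype)
    if (all(ph %in% c(0, 1))) phenoType <- "binary"
    else {
      phenoType <- "quantitative"
      ph <- ph - mean(ph)
      ph <- ph / sqrt(mean(ph^2))
    }
    cd$phenotype <- ph
  }
  g <- t(x)
  dimnames(g) <- list(snp_id, sample_ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(genotypes = g), rowData = rd, colData = cd)
  new("HarmonizedStudy", se, phenotypeType = phenoType,
      covariateNames = covNames)
}
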