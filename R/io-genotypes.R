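#' Read target-cohort genotypes
#'
#' Reads a genotype panel from PLINK BED/BIM/FAM or VCF into a
#' [GenotypePanel-class].  Dosages count copies of the coded allele: the BIM
#' A1 allele for PLINK input, the ALT allele for VCF input.  Missing
#' genotypes are `NA`, never 0.  Multi-allelic VCF records are dropped with
#' a message.  Variants are sorted to genome order.
#'
#' @param path path to the `.bed` file (companion `.bim`/`.fam` expected
#'   alongside) or to a VCF file.
#' @param format `"plink-bed"` or `"vcf"`; defaults from the file extension.
#' @param verbose print drop counts.
#'
#' @return A [GenotypePanel-class].
#' @export
readGenotypes <- function(path, format = c("auto", "plink-bed", "vcf"),
                          verbose = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path)) "plink-bed" else "vcf"
  switch(format,
         "plink-bed" = .readPlink(path),
         "vcf" = .readVcf(path, verbose = verbose))
}

.readPlink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(path, bim, fam))
    if (!file.exists(f)) stop("PLINK companion file not found: ", f)

  bimTab <- data.table::fread(bim, header = FALSE, data.table = FALSE)
  names(bimTab) <- c("chrom", "snp_id", "cm", "pos", "allele1", "allele2")
  famTab <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  sampleIds <- as.character(famTab[[2]])

  n <- length(sampleIds)
  m <- nrow(bimTab)
  bytesPerSnp <- ceiling(n / 4)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK BED file (bad magic bytes): ", path)
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major BED files are supported: ", path)
  body <- raw[-(1:3)]
  expected <- m * bytesPerSnp
  if (length(body) != expected)
    stop(sprintf(paste0("BED size mismatch: %d data bytes but %d variants x ",
                        "%d bytes expected (truncated at byte offset %d?)"),
                 length(body), m, bytesPerSnp, length(body) + 3L))

  ## 2-bit codes per individual: 00 hom A1, 10 het, 11 hom A2, 01 missing.
  ## Dosage counts A1 copies.
  lookup <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  codes <- as.integer(body)
  twoBit <- rbind(bitwAnd(codes, 3L),
                  bitwAnd(bitwShiftR(codes, 2L), 3L),
                  bitwAnd(bitwShiftR(codes, 4L), 3L),
                  bitwAnd(bitwShiftR(codes, 6L), 3L))
  dim(twoBit) <- c(4L * bytesPerSnp, m)
  dosage <- matrix(lookup[as.character(twoBit[seq_len(n), , drop = FALSE])],
                   nrow = n, ncol = m)
  variants <- data.frame(snp_id = as.character(bimTab$snp_id),
                         chrom = as.character(bimTab$chrom),
                         pos = as.integer(bimTab$pos),
                         allele1 = toupper(as.character(bimTab$allele1)),
                         allele2 = toupper(as.character(bimTab$allele2)),
                         stringsAsFactors = FALSE)
  GenotypePanel(t(dosage), variants, sampleIds)
}

.readVcf <- function(path, verbose = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi) && verbose)
    message("readGenotypes: dropped ", sum(multi), " multi-allelic record(s)")
  keep <- which(!multi)
  fmt <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                  error = function(e) NULL)
  if (!is.null(fmt) && all(is.na(fmt)))
    fmt <- NULL
  if (is.null(fmt)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ## count ALT alleles; "./." and partial missing become NA
    countAlt <- function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    }
    fmt <- matrix(vapply(gt, countAlt, numeric(1)),
                  nrow = nrow(gt), dimnames = dimnames(gt))
  }
  fmt <- fmt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  id <- ifelse(is.na(fix$ID) | fix$ID == ".",
               paste0(fix$CHROM, ":", fix$POS), fix$ID)
  variants <- data.frame(snp_id = id, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         allele1 = toupper(fix$ALT),
                         allele2 = toupper(fix$REF),
                         stringsAsFactors = FALSE)
  GenotypePanel(fmt, variants, colnames(fmt))
}

#' Write a GenotypePanel as PLINK BED/BIM/FAM
#'
#' Writes SNP-major BED with the panel's coded allele as BIM A1.  Dosages
#' are rounded to \{0, 1, 2\}; `NA` becomes the missing code.  Used by the
#' simulation module to emit cohorts every other module can read back.
#'
#' @param panel a [GenotypePanel-class].
#' @param prefix output path prefix (writes `prefix.bed/.bim/.fam`).
#'
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(panel, prefix) {
  dosage <- SummarizedExperiment::assay(panel, "dosage")  # m x n
  info <- snpInfo(panel)
  n <- ncol(dosage)
  m <- nrow(dosage)
  ## 2-bit codes: dosage counts A1 copies -> 2=00, 1=10, 0=11, NA=01
  codeOf <- c(`0` = 3L, `1` = 2L, `2` = 0L)
  bytesPerSnp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * bytesPerSnp - n
  for (j in seq_len(m)) {
    d <- round(dosage[j, ])
    code <- ifelse(is.na(d), 1L, codeOf[as.character(d)])
    code <- c(code, rep(0L, pad))
    q <- matrix(code, nrow = 4)
    byte <- q[1, ] + bitwShiftL(q[2, ], 2L) + bitwShiftL(q[3, ], 4L) +
      bitwShiftL(q[4, ], 6L)
    writeBin(as.raw(byte), con)
  }
  bim <- data.frame(info$chrom, info$snp_id, 0, info$pos, info$allele1,
                    info$allele2)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  ids <- colnames(dosage)
  fam <- data.frame(ids, ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a phenotype/covariate table keyed by sample id
#'
#' @param path delimited text file; first column (or a column named
#'   `sample_id`/`IID`) holds sample ids.
#'
#' @return A `data.frame` with rownames set to sample ids.
#' @export
readPhenotypeTable <- function(path) {
  tab <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  idCol <- intersect(c("sample_id", "IID", "iid"), names(tab))
  idCol <- if (length(idCol)) idCol[1] else names(tab)[1]
  rownames(tab) <- as.character(tab[[idCol]])
  tab[setdiff(names(tab), idCol)]
}
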