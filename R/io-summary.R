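#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a consortium-style summary-statistic table and maps its columns onto
#' the [SummaryStats-class] schema.  Rows with missing or non-finite effect
#' sizes are dropped with a message; duplicated SNP ids are an error.
#'
#' @param path path to a delimited text file (separator auto-detected).
#' @param dialect named character vector mapping schema fields to file
#'   column names.  Mandatory fields: `snp_id`, `effect_allele`,
#'   `other_allele`, `beta_ext`.  Optional: `chrom`, `pos`, `eaf`, `n_ext`.
#'   Defaults cover the common consortium layout
#'   (`MarkerName`/`Allele1`/`Allele2`/`b`/`Freq.Allele1.HapMapCEU`/`N`).
#' @param verbose print the dropped-row count.
#'
#' @return A [SummaryStats-class] table.  When the file has no coordinate
#'   columns, `chrom` is set to `"0"` and `pos` to the file row number, so
#'   downstream ordering preserves file order.
#' @export
readSummaryStats <- function(path,
                             dialect = c(snp_id = "MarkerName",
                                         effect_allele = "Allele1",
                                         other_allele = "Allele2",
                                         beta_ext = "b",
                                         eaf = "Freq.Allele1.HapMapCEU",
                                         n_ext = "N",
                                         chrom = "chr", pos = "pos"),
                             verbose = TRUE) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path)
  tab <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  mandatory <- c("snp_id", "effect_allele", "other_allele", "beta_ext")
  for (f in mandatory) {
    if (is.na(dialect[f]) || !dialect[f] %in% names(tab))
      stop("column mapping for mandatory field '", f,
           "' not found in file (looked for '", dialect[f], "')")
  }
  get <- function(f) if (!is.na(dialect[f]) && dialect[f] %in% names(tab))
    tab[[dialect[f]]] else NULL

  beta <- suppressWarnings(as.numeric(get("beta_ext")))
  keep <- !is.na(beta) & is.finite(beta)
  if (verbose && any(!keep))
    message("readSummaryStats: dropped ", sum(!keep),
            " row(s) with missing or non-finite effect size")
  dup <- duplicated(get("snp_id")[keep])
  if (any(dup))
    stop("duplicated snp_id in summary statistics: ",
         paste(unique(get("snp_id")[keep][dup]), collapse = ", "))

  chrom <- get("chrom")
  pos <- get("pos")
  if (is.null(chrom)) chrom <- rep("0", nrow(tab))
  if (is.null(pos)) pos <- seq_len(nrow(tab))
  eaf <- get("eaf")
  if (!is.null(eaf)) eaf <- suppressWarnings(as.numeric(eaf))
  n_ext <- get("n_ext")
  if (!is.null(n_ext)) n_ext <- suppressWarnings(as.numeric(n_ext))

  SummaryStats(snp_id = get("snp_id")[keep], chrom = chrom[keep],
               pos = pos[keep],
               effect_allele = get("effect_allele")[keep],
               other_allele = get("other_allele")[keep],
               beta_ext = beta[keep],
               eaf = if (is.null(eaf)) NULL else eaf[keep],
               n_ext = if (is.null(n_ext)) NULL else n_ext[keep])
}

#' Place external effect sizes on the per-SD standardized scale
#'
#' External coefficients are assumed standardized for reference allele
#' frequency; when they are instead reported per allele copy, each beta is
#' rescaled by the genotype SD implied by its allele frequency under
#' Hardy-Weinberg equilibrium, `sqrt(2 * eaf * (1 - eaf))`.
#'
#' @param stats a [SummaryStats-class] table.
#' @param mode `"already-standardized"` (identity) or `"per-allele"`
#'   (requires the `eaf` column; SNPs with `eaf` of exactly 0 or 1 are
#'   dropped with a message).
#' @param verbose print the dropped-SNP count.
#'
#' @return A [SummaryStats-class] table with `beta_ext` on the per-SD scale.
#' @export
standardizeBetas <- function(stats,
                             mode = c("already-standardized", "per-allele"),
                             verbose = TRUE) {
  mode <- match.arg(mode)
  if (mode == "already-standardized") return(stats)
  if (!"eaf" %in% colnames(stats))
    stop("per-allele standardization requires the eaf column")
  df <- as(stats, "DFrame")
  eaf <- df$eaf
  bad <- is.na(eaf) | eaf <= 0 | eaf >= 1
  if (any(bad)) {
    if (verbose)
      message("standardizeBetas: dropped ", sum(bad),
              " SNP(s) with missing or degenerate allele frequency")
    df <- df[!bad, , drop = FALSE]
    eaf <- eaf[!bad]
  }
  df$beta_ext <- df$beta_ext * sqrt(2 * eaf * (1 - eaf))
  new("SummaryStats", df)
}
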