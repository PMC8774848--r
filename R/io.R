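#' Write summary statistics to a tab-delimited file
#'
#' Uses the conventional column header `SNP CHR BP A1 A2 FRQ BETA SE Z P N`.
#'
#' @param sumstats A [SumStats-class] or data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSumStats <- function(sumstats, path) {
  df <- as.data.frame(sumstats)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read summary statistics from a tab-delimited file
#'
#' @param path File written by [writeSumStats()] (or any table with the
#'   standard columns).
#' @return A [SumStats-class] object.
#' @export
readSumStats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  df$CHR <- as.character(df$CHR)
  SumStats(df)
}

#' Write genotypes to a VCF 4.2 file
#'
#' Emits hard genotype calls (GT field) for integer dosages, coding the ALT
#' allele count (0 = `0/0`, 1 = `0/1`, 2 = `1/1`, `NA` = `./.`). Output is
#' deterministic: the same data always produce byte-identical files.
#'
#' @param genotypes A [GenotypeData-class] with integer dosages.
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(genotypes, path) {
  D <- dosages(genotypes)
  vi <- variantInfo(genotypes)
  if (any(round(D) != D, na.rm = TRUE))
    stop("VCF GT output requires integer dosages")
  gtCodes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gwasubtract",
    '##INFO=<ID=INFO,Number=1,Type=Float,Description="Imputation INFO score">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(D)), collapse = "\t"))
  gt <- matrix(gtCodes[round(D) + 1L], nrow = nrow(D))
  gt[is.na(D)] <- "./."
  body <- paste(vi$CHR, vi$BP, vi$SNP, vi$REF, vi$ALT, ".", "PASS",
                sprintf("INFO=%g", vi$INFO), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF with `vcfR` and converts GT calls to ALT-allele dosages.
#'
#' @param path Path to a VCF file.
#' @return A [GenotypeData-class] object.
#' @export
readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count <- function(x) {
    ifelse(x %in% c("0/0", "0|0"), 0L,
      ifelse(x %in% c("0/1", "1/0", "0|1", "1|0"), 1L,
        ifelse(x %in% c("1/1", "1|1"), 2L, NA_integer_)))
  }
  D <- apply(gt, 2L, count)
  fix <- vcfR::getFIX(v)
  info <- v@fix[, "INFO"]
  infoScore <- suppressWarnings(
    as.numeric(sub(".*INFO=([0-9eE.+-]+).*", "\\1", info)))
  infoScore[is.na(infoScore)] <- 1
  GenotypeData(D, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
               id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
               info = infoScore, sampleIds = colnames(gt))
}

#' Export a simulated study as plain-text fixtures
#'
#' Writes the genotypes as VCF 4.2, the covariate/phenotype table and the
#' per-variant truth table as tab-delimited files. Given identical inputs the
#' files are byte-identical (numbers are formatted with fixed precision).
#'
#' @param genotypes A [GenotypeData-class].
#' @param cohort The cohort data.frame.
#' @param truth The truth data.frame (`SNP, BETA_E_TRUE, BETA_R_TRUE`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
exportFixtures <- function(genotypes, cohort, truth, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             cohort = file.path(dir, "cohort.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeGenotypesVcf(genotypes, paths["vcf"])
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    df
  }
  writeTsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(fmt(df), con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  writeTsv(cohort, paths["cohort"])
  writeTsv(truth, paths["truth"])
  invisible(paths)
}
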