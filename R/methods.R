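#' Construct a GenotypeData object
#'
#' @param dosage Numeric matrix, variants x samples, entries in `[0, 2]`
#'   (hard genotypes or imputed dosages) or `NA`.
#' @param chrom Chromosome per variant.
#' @param pos 1-based position per variant.
#' @param id Variant id per variant.
#' @param ref,alt Reference / alternate (effect) allele per variant.
#' @param info Imputation INFO score per variant (default 1, directly typed).
#' @param sampleIds Sample identifiers (default `S1..Sn`).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, chrom, pos, id, ref, alt,
                         info = rep(1, nrow(dosage)),
                         sampleIds = NULL) {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage)
  stopifnot(length(chrom) == m, length(pos) == m, length(id) == m,
            length(ref) == m, length(alt) == m)
  if (is.null(sampleIds)) {
    sampleIds <- colnames(dosage)
    if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(ncol(dosage)))
  }
  dimnames(dosage) <- list(id, sampleIds)
  rr <- GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(pos), width = 1L),
    SNP = as.character(id), REF = as.character(ref), ALT = as.character(alt),
    INFO = as.numeric(info)
  )
  names(rr) <- id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dosage = dosage), rowRanges = rr)
  methods::new("GenotypeData", se)
}

#' @rdname GenotypeData-class
#' @export
setMethod("dosages", "GenotypeData", function(x)
  SummarizedExperiment::assay(x, "dosage"))

#' @rdname GenotypeData-class
#' @export
setMethod("variantInfo", "GenotypeData", function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  d <- dosages(x)
  af <- rowMeans(d, na.rm = TRUE) / 2  # ALT allele frequency
  data.frame(
    SNP = S4Vectors::mcols(rr)$SNP,
    CHR = as.character(GenomicRanges::seqnames(rr)),
    BP = GenomicRanges::start(rr),
    REF = S4Vectors::mcols(rr)$REF,
    ALT = S4Vectors::mcols(rr)$ALT,
    ALT_FRQ = af,
    MAF = pmin(af, 1 - af),
    INFO = S4Vectors::mcols(rr)$INFO,
    row.names = NULL, stringsAsFactors = FALSE
  )
})

#' @rdname GenotypeData-class
#' @export
setMethod("snpIds", "GenotypeData", function(x)
  S4Vectors::mcols(SummarizedExperiment::rowRanges(x))$SNP)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
  methods::callNextMethod()
})

#' Construct a SumStats table
#'
#' @param df A data.frame (or DataFrame) with columns
#'   `SNP CHR BP A1 A2 FRQ BETA SE Z P N` (extra columns such as `INFO` or
#'   `FLAG` are kept).
#' @return A [SumStats-class] object.
#' @export
SumStats <- function(df) {
  df <- S4Vectors::DataFrame(df)
  miss <- setdiff(.sumstats_cols, colnames(df))
  if (length(miss))
    stop("SumStats is missing columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(colnames(df), .sumstats_cols)
  methods::new("SumStats", df[, c(.sumstats_cols, extra)])
}

setMethod("show", "SumStats", function(object) {
  cat("SumStats with", nrow(object), "variants\n")
  print(utils::head(as.data.frame(object), 5L))
  if (nrow(object) > 5L) cat("...\n")
})

#' @rdname GeneticCovariance-class
#' @export
setMethod("geneticCovariance", "GeneticCovariance", function(x) x@S)

#' @rdname GeneticCovariance-class
#' @export
setMethod("samplingCovariance", "GeneticCovariance", function(x) x@V)

#' @rdname GeneticCovariance-class
#' @export
setMethod("geneticCorrelation", "GeneticCovariance", function(x)
  c(rg = x@rg, se = x@rgSE, p = x@rgP))

setMethod("show", "GeneticCovariance", function(object) {
  cat("GeneticCovariance (", paste(object@traits, collapse = " / "), ")\n",
      sep = "")
  cat("S:\n"); print(round(object@S, 5))
  cat(sprintf("h2 SEs: %.4g, %.4g\n", object@h2SE[1], object@h2SE[2]))
  cat(sprintf("rg = %.4f (SE %.4f, p = %.3g)\n",
              object@rg, object@rgSE, object@rgP))
  cat(sprintf("intercepts: %s\n",
              paste(sprintf("%s=%.3f", names(object@intercepts),
                            object@intercepts), collapse = ", ")))
  cat(sprintf("M = %d variants, %d jackknife blocks\n",
              as.integer(object@M), object@nBlocks))
})

#' @rdname CholeskyLoadings-class
#' @export
setMethod("pathLoadings", "CholeskyLoadings", function(x)
  c(lambdaEduEyres = x@lambdaEduEyres,
    lambdaEduNonres = x@lambdaEduNonres,
    lambdaResEyres = x@lambdaResEyres))

setMethod("show", "CholeskyLoadings", function(object) {
  l <- pathLoadings(object)
  se <- sqrt(pmax(diag(object@vcov), 0))
  cat("Cholesky path loadings (GWAS-by-subtraction)\n")
  for (i in seq_along(l))
    cat(sprintf("  %-16s %8.5f (SE %.5f)\n", names(l)[i], l[i], se[i]))
})

#' @rdname LatentSumStats-class
#' @export
setMethod("resilienceStats", "LatentSumStats", function(x) x@resilience)

#' @rdname LatentSumStats-class
#' @export
setMethod("eduYearsStats", "LatentSumStats", function(x) x@eduYears)

#' @rdname LatentSumStats-class
#' @export
setMethod("effectiveSampleSizes", "LatentSumStats", function(x) x@neff)

setMethod("show", "LatentSumStats", function(object) {
  cat("LatentSumStats:", nrow(object@resilience), "variants;",
      object@nDropped, "dropped in harmonisation\n")
  cat(sprintf("effective N: Resilience = %d, EduYears = %d\n",
              round(object@neff["resilience"]), round(object@neff["eduYears"])))
  show(object@loadings)
})

#' @rdname LocusTable-class
#' @export
setMethod("lociTable", "LocusTable", function(x) x@table)

#' @rdname LocusTable-class
#' @export
setMethod("lociRanges", "LocusTable", function(x) x@loci)

#' @rdname LocusTable-class
#' @export
setMethod("leadSnps", "LocusTable", function(x) x@leadSnps)

#' @rdname LocusTable-class
#' @export
setMethod("independentSnps", "LocusTable", function(x) x@independentSnps)

setMethod("show", "LocusTable", function(object) {
  cat("LocusTable:", nrow(object@table), "loci,",
      length(object@leadSnps), "lead SNPs,",
      length(object@independentSnps), "independent significant SNPs\n")
  print(object@table)
})
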