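#' Case-control GWAS of one quadrant contrast
#'
#' Subsets the cohort to the case and control quadrant groups of the
#' requested contrast, codes cases as 1, and runs the covariate-adjusted
#' logistic GWAS.
#'
#' @param genotypes A [GenotypeData-class] whose samples match `cohort$IID`.
#' @param cohort A cohort data.frame with a `GROUP` column (from
#'   [assignQuadrants()]).
#' @param contrast `"eyres"` (EY+Res: resilient cases vs declining controls)
#'   or `"nonres"` (EY/NonRes: consistently-low cases vs consistently-high
#'   controls).
#' @param covars Covariate column names (see [covariateMatrix()]).
#' @return A [SumStats-class].
#' @export
quadrantGwas <- function(genotypes, cohort, contrast = c("eyres", "nonres"),
                         covars = c("SEX", "AGE", "CENTRE", "ARRAY",
                                    paste0("PC", 1:8))) {
  contrast <- match.arg(contrast)
  groups <- switch(contrast,
                   eyres = c("EYRES_CASE", "EYRES_CONTROL"),
                   nonres = c("NONRES_CASE", "NONRES_CONTROL"))
  sub <- cohort[!is.na(cohort$GROUP) & cohort$GROUP %in% groups, ,
                drop = FALSE]
  if (!nrow(sub)) stop("no individuals in the requested contrast")
  idx <- match(sub$IID, colnames(genotypes))
  if (anyNA(idx)) stop("cohort IIDs missing from the genotype samples")
  g <- genotypes[, idx]
  y <- as.integer(sub$GROUP == groups[1])
  runGWAS(g, y, covariates = covariateMatrix(sub, covars),
          model = "logistic")
}

#' Run the full GWAS-by-subtraction pipeline on one cohort
#'
#' End-to-end: derived phenotypes and quadrant groups, the two quadrant
#' contrast GWAS, LD scores from the genotypes themselves, munging, bivariate
#' LD-score regression (S and V), Cholesky loadings, per-SNP subtraction into
#' latent Resilience/EduYears summary statistics with effective sample sizes,
#' and the post-subtraction genetic correlation between the two latent
#' traits (which the subtraction should drive to zero).
#'
#' @param genotypes A [GenotypeData-class].
#' @param cohort The matching covariate/phenotype data.frame.
#' @param windowKb LD-score window, kb.
#' @param minMaf Munging MAF filter.
#' @param nBlocks Jackknife blocks for the LDSC fits.
#' @return A list: `cohort` (with derived columns), `rtModel`, `gwasEyres`,
#'   `gwasNonres`, `ldscores`, `gcov` ([GeneticCovariance-class]),
#'   `loadings` ([CholeskyLoadings-class]), `latent`
#'   ([LatentSumStats-class]), and `rgLatent` (the post-subtraction
#'   [GeneticCovariance-class] between Resilience and EduYears).
#' @export
runSubtractionPipeline <- function(genotypes, cohort, windowKb = 1000,
                                   minMaf = 0.01, nBlocks = 200L) {
  ph <- buildPhenotypes(cohort)
  gEyres <- quadrantGwas(genotypes, ph$cohort, "eyres")
  gNonres <- quadrantGwas(genotypes, ph$cohort, "nonres")
  ld <- computeLDScores(genotypes, windowKb = windowKb)
  mEyres <- mungeSumstats(gEyres, genotypes, minMaf = minMaf)
  mNonres <- mungeSumstats(gNonres, genotypes, minMaf = minMaf)
  gcov <- ldscRG(mEyres, mNonres, ld, nBlocks = nBlocks,
                 traits = c("EY+Res", "EY/NonRes"))
  loadings <- fitCholesky(gcov)
  latent <- gwasBySubtraction(mEyres, mNonres, loadings, genotypes,
                              crossIntercept = 0)
  mRes <- mungeSumstats(resilienceStats(latent), genotypes, minMaf = minMaf)
  mEdu <- mungeSumstats(eduYearsStats(latent), genotypes, minMaf = minMaf)
  rgLatent <- ldscRG(mRes, mEdu, ld, nBlocks = nBlocks,
                     traits = c("Resilience", "EduYears"))
  list(cohort = ph$cohort, rtModel = ph$rtModel,
       gwasEyres = gEyres, gwasNonres = gNonres, ldscores = ld,
       gcov = gcov, loadings = loadings, latent = latent,
       rgLatent = rgLatent)
}
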