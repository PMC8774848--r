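#' @import methods
#' @importFrom stats coef cor cov lm.wfit median pbinom pnorm qnorm rbinom
#'   rnorm runif sd setNames var complete.cases
#' @importFrom utils head
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' Simulation configuration for a synthetic cohort
#'
#' Parameters of the synthetic-cohort generator. Defaults correspond to the
#' desk-scale study conditions used throughout the package's validation suite:
#' a middle-aged cohort (ages 40-69) of 20,000 individuals typed at 2,000
#' variants, with two independent latent genetic factors -- an education-years
#' factor (heritability `h2Edu = 0.3`) shared by both quadrant contrasts and a
#' processing-speed resilience factor (`h2Res = 0.2`) loading only on reaction
#' time.
#'
#' @slot nIndividuals Number of individuals.
#' @slot nSnps Number of variants.
#' @slot mafRange Length-2 numeric in (0, 0.5]; per-variant minor allele
#'   frequencies are drawn uniformly from this interval.
#' @slot nCausalEdu,nCausalRes Number of causal variants per factor
#'   (`NA_integer_` means all variants are causal, the polygenic default).
#' @slot h2Edu,h2Res Heritability of each latent factor, in `[0, 1]`.
#' @slot ageRange Length-2 integer age range in years (inclusive).
#' @slot rtAgeSlope Reaction-time slope on age, ms per year (>= 0).
#' @slot rtBase Baseline mean reaction time in ms at the mean age.
#' @slot kappaEdu,kappaRes Weights (ms per factor SD) with which the latent
#'   factors speed up reaction time: higher factor scores give faster
#'   (smaller) RT.
#' @slot noiseSdRt Residual reaction-time SD in ms.
#' @slot noiseSdEy Extra jitter SD applied to the education liability before
#'   the quantile mapping onto years (0 disables).
#' @slot collegeRate Fraction of the cohort flagged as college attendees
#'   (top of the education liability; their years are recorded as missing,
#'   mirroring how the source cohort records education).
#' @slot ldRho Haplotype-level AR(1) latent correlation between adjacent
#'   variants within an LD block (0 = independent sites).
#' @slot ldBlockSize Number of adjacent variants per LD block.
#' @slot posSpacing Base-pair spacing between adjacent variants.
#' @slot nCentres Number of assessment centres (nuisance covariate levels).
#' @slot seed Master seed; per-stage child seeds are derived from it.
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer", nSnps = "integer", mafRange = "numeric",
    nCausalEdu = "integer", nCausalRes = "integer",
    h2Edu = "numeric", h2Res = "numeric",
    ageRange = "integer", rtAgeSlope = "numeric", rtBase = "numeric",
    kappaEdu = "numeric", kappaRes = "numeric",
    noiseSdRt = "numeric", noiseSdEy = "numeric", collegeRate = "numeric",
    ldRho = "numeric", ldBlockSize = "integer", posSpacing = "integer",
    nCentres = "integer", seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nIndividuals <= 0L) msg <- c(msg, "nIndividuals must be > 0")
  if (object@nSnps <= 0L) msg <- c(msg, "nSnps must be > 0")
  if (length(object@mafRange) != 2L ||
      any(object@mafRange <= 0) || any(object@mafRange > 0.5) ||
      object@mafRange[1] > object@mafRange[2])
    msg <- c(msg, "mafRange must be an ordered pair in (0, 0.5]")
  for (nm in c("h2Edu", "h2Res")) {
    v <- slot(object, nm)
    if (v < 0 || v > 1) msg <- c(msg, paste(nm, "must be in [0, 1]"))
  }
  for (nm in c("nCausalEdu", "nCausalRes")) {
    v <- slot(object, nm)
    if (!is.na(v) && (v < 1L || v > object@nSnps))
      msg <- c(msg, paste(nm, "must be in 1..nSnps"))
  }
  if (object@ageRange[1] > object@ageRange[2])
    msg <- c(msg, "ageRange must be ordered")
  if (object@rtAgeSlope < 0) msg <- c(msg, "rtAgeSlope must be >= 0")
  if (object@ldRho < 0 || object@ldRho >= 1)
    msg <- c(msg, "ldRho must be in [0, 1)")
  if (object@collegeRate < 0 || object@collegeRate >= 1)
    msg <- c(msg, "collegeRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Genotype dosages with variant metadata
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] with one assay,
#' `"dosage"` (variants x samples, values in `[0, 2]` or `NA`), and variant
#' metadata (`SNP`, `REF`, `ALT`, `INFO`) on the row ranges. Doubles as the
#' LD reference panel for LD scores and clumping.
#'
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- SummarizedExperiment::assay(object, "dosage")
  rng <- suppressWarnings(range(d, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    return("dosages must lie in [0, 2]")
  need <- c("SNP", "REF", "ALT")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    return(paste("missing rowData columns:", paste(miss, collapse = ", ")))
  TRUE
})

#' Per-variant association summary statistics
#'
#' A [S4Vectors::DataFrame] subclass with the canonical column set
#' `SNP CHR BP A1 A2 FRQ BETA SE Z P N` (A1 is the effect allele; BETA is the
#' log-odds per A1 allele for binary traits). An optional `FLAG` column marks
#' variants where the fit was degenerate (`"nonconverged"`, `"collinear"`).
#'
#' @export
setClass("SumStats", contains = "DFrame")

.sumstats_cols <- c("SNP", "CHR", "BP", "A1", "A2", "FRQ",
                    "BETA", "SE", "Z", "P", "N")

setValidity("SumStats", function(object) {
  miss <- setdiff(.sumstats_cols, colnames(object))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  frq <- object$FRQ
  if (any(!is.na(frq) & (frq <= 0 | frq >= 1)))
    return("FRQ must lie in (0, 1)")
  TRUE
})

#' Genetic covariance of two traits from LD-score regression
#'
#' Holds the 2x2 genetic covariance matrix `S`, the 3x3 block-jackknife
#' sampling covariance `V` of its unique elements (half-vectorised order
#' S11, S12, S22), the univariate and cross-trait regression intercepts, the
#' number of regression variants `M`, and the genetic correlation with its
#' jackknife SE.
#'
#' @slot S 2x2 genetic covariance matrix.
#' @slot V 3x3 sampling covariance of (S11, S12, S22).
#' @slot intercepts Named numeric: univariate intercepts and cross-trait
#'   intercept.
#' @slot M Number of variants used in the regressions.
#' @slot nBlocks Number of jackknife blocks actually used.
#' @slot traits Trait labels (length 2).
#' @slot rg Genetic correlation S12 / sqrt(S11 S22).
#' @slot rgSE Block-jackknife SE of `rg`.
#' @slot rgP Two-sided normal p-value for rg = 0.
#' @slot h2SE Jackknife SEs of the diagonal of S.
#' @export
setClass("GeneticCovariance",
  representation(S = "matrix", V = "matrix", intercepts = "numeric",
                 M = "numeric", nBlocks = "integer", traits = "character",
                 rg = "numeric", rgSE = "numeric", rgP = "numeric",
                 h2SE = "numeric")
)

setValidity("GeneticCovariance", function(object) {
  if (!all(dim(object@S) == c(2L, 2L))) return("S must be 2x2")
  if (!all(dim(object@V) == c(3L, 3L))) return("V must be 3x3")
  if (abs(object@S[1, 2] - object@S[2, 1]) > 1e-8)
    return("S must be symmetric")
  TRUE
})

#' Cholesky path loadings of the GWAS-by-subtraction model
#'
#' Loadings of the two observed quadrant contrasts on the latent EduYears and
#' Resilience factors: EduYears loads on both contrasts, Resilience only on
#' the resilient contrast, and the implied covariance reconstructs `S`
#' exactly (the model is just-identified).
#'
#' @slot lambdaEduEyres Loading of EduYears on the EY+Res contrast.
#' @slot lambdaEduNonres Loading of EduYears on the EY/NonRes contrast.
#' @slot lambdaResEyres Loading of Resilience on the EY+Res contrast.
#' @slot vcov 3x3 delta-method sampling covariance of the loadings, order
#'   (lambdaEduEyres, lambdaEduNonres, lambdaResEyres).
#' @slot S The 2x2 genetic covariance the loadings were derived from.
#' @export
setClass("CholeskyLoadings",
  representation(lambdaEduEyres = "numeric", lambdaEduNonres = "numeric",
                 lambdaResEyres = "numeric", vcov = "matrix", S = "matrix")
)

#' Latent-trait summary statistics from GWAS-by-subtraction
#'
#' Per-variant effects of each SNP on the latent Resilience and EduYears
#' factors, as [SumStats] tables, together with the loadings used and the
#' effective sample sizes written into the `N` columns.
#'
#' @slot resilience [SumStats] for the latent Resilience factor.
#' @slot eduYears [SumStats] for the latent EduYears factor.
#' @slot loadings The [CholeskyLoadings] used in the subtraction.
#' @slot neff Named numeric: effective N of each latent trait.
#' @slot nDropped Number of variants dropped during harmonisation.
#' @export
setClass("LatentSumStats",
  representation(resilience = "SumStats", eduYears = "SumStats",
                 loadings = "CholeskyLoadings", neff = "numeric",
                 nDropped = "integer")
)

#' Genomic loci from two-stage LD clumping
#'
#' Independent significant SNPs (r^2 < 0.6 clumping at p < 5e-8), lead SNPs
#' (second-stage clumping at r^2 < 0.1), and merged genomic loci (candidate
#' hulls merged when separated by at most 250 kb), following the two-stage
#' locus definition convention.
#'
#' @slot table Per-locus summary data.frame (LOCUS, CHR, START, END,
#'   INDEX_SNP, INDEX_P, N_LEAD, N_IND_SIG, N_CANDIDATE).
#' @slot loci [GenomicRanges::GRanges] of the merged loci.
#' @slot independentSnps Character vector of independent significant SNP ids.
#' @slot leadSnps Character vector of lead SNP ids.
#' @slot candidateSnps List (one element per locus) of candidate SNP ids.
#' @slot nMissingFromReference Significant SNPs absent from the LD reference
#'   (retained as independent, with a warning).
#' @export
setClass("LocusTable",
  representation(table = "data.frame", loci = "GRanges",
                 independentSnps = "character", leadSnps = "character",
                 candidateSnps = "list", nMissingFromReference = "integer")
)
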