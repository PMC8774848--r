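#' Fit the Cholesky path loadings from a genetic covariance matrix
#'
#' The GWAS-by-subtraction model regresses both observed contrasts on a
#' latent EduYears factor (capturing their shared genetic variance) and the
#' resilient contrast additionally on a latent Resilience factor, with the
#' two latent factors uncorrelated and the contrasts' residual variances
#' fixed to zero. The model is just-identified, so the loadings are the
#' Cholesky factor of `S` in closed form:
#' `lambdaEduNonres = sqrt(S22)`, `lambdaEduEyres = S12 / sqrt(S22)`,
#' `lambdaResEyres = sqrt(S11 - S12^2 / S22)` (a numerical weighted
#' least-squares fit of the same model coincides with these values). Loading
#' sampling covariance follows by the delta method from `V`.
#'
#' @param gcov A [GeneticCovariance-class] with `S` ordered
#'   (EY+Res, EY/NonRes).
#' @return A [CholeskyLoadings-class] object.
#' @export
fitCholesky <- function(gcov) {
  S <- geneticCovariance(gcov)
  V <- samplingCovariance(gcov)
  s11 <- S[1, 1]; s12 <- S[1, 2]; s22 <- S[2, 2]
  if (s22 <= 0)
    stop("S22 <= 0: the EduYears factor is undefined")
  if (s11 <= 0)
    stop("S11 <= 0: the EY+Res genetic variance is non-positive")
  resVar <- s11 - s12^2 / s22
  if (resVar < 0)
    stop("S is not positive semidefinite (S11 - S12^2/S22 < 0); ",
         "the subtraction model is inadmissible")
  lEduNon <- sqrt(s22)
  lEduEy <- s12 / lEduNon
  lResEy <- sqrt(resVar)
  # Jacobian of (lEduEy, lEduNon, lResEy) wrt (S11, S12, S22)
  J <- rbind(
    c(0, 1 / lEduNon, -s12 / (2 * s22^1.5)),
    c(0, 0, 1 / (2 * lEduNon)),
    if (lResEy > 0)
      c(1 / (2 * lResEy), -s12 / (s22 * lResEy),
        s12^2 / (2 * s22^2 * lResEy))
    else c(0, 0, 0)
  )
  vc <- J %*% V %*% t(J)
  dimnames(vc) <- list(
    c("lambdaEduEyres", "lambdaEduNonres", "lambdaResEyres"),
    c("lambdaEduEyres", "lambdaEduNonres", "lambdaResEyres"))
  methods::new("CholeskyLoadings",
               lambdaEduEyres = lEduEy, lambdaEduNonres = lEduNon,
               lambdaResEyres = lResEy, vcov = vc, S = S)
}

#' GWAS-by-subtraction: latent Resilience and EduYears summary statistics
#'
#' Converts the two observed contrast GWAS to standardized per-variant
#' effects `b = Z / sqrt(N * 2pq)` (variant variance `2pq` from the supplied
#' allele-frequency reference), then solves the just-identified path system
#' per variant: `betaEdu = b2 / lambdaEduNonres` and
#' `betaRes = (b1 - lambdaEduEyres * betaEdu) / lambdaResEyres`. Standard
#' errors follow by the delta method from the sampling variances
#' `1 / (N * 2pq)` and the cross-trait covariance implied by the LDSC
#' cross-trait intercept (`crossIntercept / sqrt(N1 N2) / 2pq`); sampling
#' uncertainty in the genome-wide loadings can optionally be propagated as
#' well. Effective sample sizes are computed with [effectiveN()] and written
#' into the `N` columns.
#'
#' @param eyres,nonres Munged summary statistics of the EY+Res and EY/NonRes
#'   contrasts (columns `SNP, A1, A2, Z, N`), aligned to the same reference.
#' @param loadings A [CholeskyLoadings-class] from [fitCholesky()].
#' @param freqRef Allele-frequency reference: a [GenotypeData-class] or a
#'   data.frame `SNP, A1, A2, FRQ` (`FRQ` = frequency of `A1`).
#' @param crossIntercept LDSC cross-trait intercept used for the per-variant
#'   sampling covariance of the two observed effects; 0 (the default) is
#'   appropriate when the two contrasts use disjoint individuals.
#' @param includeLoadingUncertainty Propagate the loadings' sampling
#'   covariance into the per-variant SEs (default `FALSE`: genome-wide
#'   loadings are treated as fixed).
#' @return A [LatentSumStats-class] object.
#' @export
gwasBySubtraction <- function(eyres, nonres, loadings, freqRef,
                              crossIntercept = 0,
                              includeLoadingUncertainty = FALSE) {
  lEduEy <- loadings@lambdaEduEyres
  lEduNon <- loadings@lambdaEduNonres
  lResEy <- loadings@lambdaResEyres
  if (lResEy == 0)
    stop("lambdaResEyres is 0: the subtraction is undefined")
  if (lEduNon == 0)
    stop("lambdaEduNonres is 0: the EduYears factor is undefined")

  s1 <- as.data.frame(eyres)
  s2 <- as.data.frame(nonres)
  if (methods::is(freqRef, "GenotypeData")) {
    vi <- variantInfo(freqRef)
    fr <- data.frame(SNP = vi$SNP, A1 = vi$ALT, A2 = vi$REF,
                     FRQ = vi$ALT_FRQ, CHR = vi$CHR, BP = vi$BP,
                     stringsAsFactors = FALSE)
  } else {
    fr <- as.data.frame(freqRef)
  }
  nIn <- nrow(s1)
  i2 <- match(s1$SNP, s2$SNP)
  iF <- match(s1$SNP, fr$SNP)
  ok <- !is.na(i2) & !is.na(iF) & !is.na(s1$Z)
  s1 <- s1[ok, , drop = FALSE]
  s2 <- s2[i2[ok], , drop = FALSE]
  fr <- fr[iF[ok], , drop = FALSE]
  ok2 <- !is.na(s2$Z) &
    ((s1$A1 == s2$A1 & s1$A2 == s2$A2) | (s1$A1 == s2$A2 & s1$A2 == s2$A1)) &
    ((s1$A1 == fr$A1 & s1$A2 == fr$A2) | (s1$A1 == fr$A2 & s1$A2 == fr$A1))
  s1 <- s1[ok2, , drop = FALSE]; s2 <- s2[ok2, , drop = FALSE]
  fr <- fr[ok2, , drop = FALSE]
  if (!nrow(s1)) stop("no variants shared across inputs and reference")
  # harmonise everything to s1's allele orientation
  z2 <- ifelse(s1$A1 == s2$A1, s2$Z, -s2$Z)
  p1 <- ifelse(s1$A1 == fr$A1, fr$FRQ, 1 - fr$FRQ)
  nDropped <- nIn - nrow(s1)

  h2pq <- 2 * p1 * (1 - p1)
  b1 <- s1$Z / sqrt(s1$N * h2pq)
  b2 <- z2 / sqrt(s2$N * h2pq)
  v1 <- 1 / (s1$N * h2pq)
  v2 <- 1 / (s2$N * h2pq)
  c12 <- crossIntercept / (sqrt(s1$N * s2$N) * h2pq)

  betaEdu <- b2 / lEduNon
  betaRes <- (b1 - lEduEy * betaEdu) / lResEy
  k <- lEduEy / lEduNon
  varEdu <- v2 / lEduNon^2
  varRes <- (v1 + k^2 * v2 - 2 * k * c12) / lResEy^2

  if (includeLoadingUncertainty) {
    VL <- loadings@vcov
    # gradients wrt (lEduEy, lEduNon, lResEy)
    gEdu <- cbind(0, -b2 / lEduNon^2, 0)
    gRes <- cbind(-betaEdu / lResEy,
                  lEduEy * b2 / (lEduNon^2 * lResEy),
                  -betaRes / lResEy)
    varEdu <- varEdu + rowSums((gEdu %*% VL) * gEdu)
    varRes <- varRes + rowSums((gRes %*% VL) * gRes)
  }

  seEdu <- sqrt(varEdu)
  seRes <- sqrt(varRes)
  zEdu <- betaEdu / seEdu
  zRes <- betaRes / seRes

  chr <- if ("CHR" %in% names(s1)) s1$CHR else
    if ("CHR" %in% names(fr)) fr$CHR else NA
  bp <- if ("BP" %in% names(s1)) s1$BP else
    if ("BP" %in% names(fr)) fr$BP else NA

  tryNeff <- function(beta, z) {
    tryCatch(effectiveN(data.frame(FRQ = p1, BETA = beta, Z = z)),
             error = function(e) {
               warning("effective N undefined: ", conditionMessage(e))
               NA_real_
             })
  }
  neffRes <- tryNeff(betaRes, zRes)
  neffEdu <- tryNeff(betaEdu, zEdu)
  mk <- function(beta, se, z, neff) {
    SumStats(data.frame(
      SNP = s1$SNP, CHR = chr, BP = bp, A1 = s1$A1, A2 = s1$A2,
      FRQ = p1, BETA = beta, SE = se, Z = z, P = zToP(z),
      N = rep(neff, length(beta)), stringsAsFactors = FALSE))
  }
  res <- mk(betaRes, seRes, zRes, neffRes)
  edu <- mk(betaEdu, seEdu, zEdu, neffEdu)
  methods::new("LatentSumStats",
               resilience = res, eduYears = edu, loadings = loadings,
               neff = c(resilience = neffRes, eduYears = neffEdu),
               nDropped = as.integer(nDropped))
}

#' Effective sample size of a latent-trait GWAS
#'
#' Inverts the standardization `Z = beta * sqrt(N * 2pq)` per variant:
#' `Nhat = (Z / beta)^2 / (2 * MAF * (1 - MAF))`, averaged over variants with
#' MAF strictly between `mafLo` and `mafHi` (low and high MAF bias the
#' result, hence the trim). Variants with `beta = 0` are excluded.
#'
#' @param latent A [SumStats-class] (or data.frame) with `FRQ, BETA, Z`.
#' @param mafLo,mafHi MAF trim bounds (defaults 0.10 and 0.40, exclusive).
#' @return The effective sample size (mean of the per-variant values).
#' @export
effectiveN <- function(latent, mafLo = 0.10, mafHi = 0.40) {
  d <- as.data.frame(latent)
  maf <- pmin(d$FRQ, 1 - d$FRQ)
  keep <- !is.na(maf) & maf > mafLo & maf < mafHi &
    !is.na(d$BETA) & d$BETA != 0
  if (!any(keep)) stop("no variants inside the MAF trim window")
  nhat <- (d$Z[keep] / d$BETA[keep])^2 / (2 * maf[keep] * (1 - maf[keep]))
  mean(nhat)
}
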