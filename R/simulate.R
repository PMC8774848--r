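#' Create a simulation configuration
#'
#' Builds a validated [SimulationConfig-class]. The defaults describe the
#' desk-scale study conditions used by the package's validation suite: 20,000
#' individuals aged 40-69, 2,000 variants with allele frequencies uniform on
#' (0.05, 0.5), fully polygenic architecture, education-factor heritability
#' 0.3 and resilience-factor heritability 0.2, reaction time rising 3 ms per
#' year of age around a 530 ms baseline, and both latent factors speeding up
#' reaction time (higher score = faster).
#'
#' @param nIndividuals,nSnps Cohort and panel sizes.
#' @param mafRange Pair of allele frequencies in (0, 0.5].
#' @param nCausalEdu,nCausalRes Causal variant counts (`NA` = all variants).
#' @param h2Edu,h2Res Factor heritabilities in `[0, 1]`.
#' @param ageRange Age range in years (inclusive).
#' @param rtAgeSlope Reaction-time slope on age, ms/year.
#' @param rtBase Baseline reaction time, ms.
#' @param kappaEdu,kappaRes Factor-to-RT weights, ms per factor SD.
#' @param noiseSdRt Residual RT standard deviation, ms.
#' @param noiseSdEy Extra education-liability jitter SD.
#' @param collegeRate Fraction flagged as college attendees, in `[0, 0.5)`.
#' @param ldRho AR(1) haplotype correlation between adjacent variants within
#'   an LD block (0 = independent sites).
#' @param ldBlockSize Variants per LD block when `ldRho > 0`.
#' @param posSpacing Base pairs between adjacent variants.
#' @param nCentres Number of assessment centres.
#' @param seed Master seed (per-stage child seeds are derived from it).
#' @return A [SimulationConfig-class] object.
#' @export
simulationConfig <- function(nIndividuals = 20000L, nSnps = 2000L,
                             mafRange = c(0.05, 0.5),
                             nCausalEdu = NA_integer_, nCausalRes = NA_integer_,
                             h2Edu = 0.3, h2Res = 0.2,
                             ageRange = c(40L, 69L),
                             rtAgeSlope = 3, rtBase = 530,
                             kappaEdu = 30, kappaRes = 60,
                             noiseSdRt = 80, noiseSdEy = 0,
                             collegeRate = 0.2,
                             ldRho = 0, ldBlockSize = 25L,
                             posSpacing = 25000L,
                             nCentres = 10L, seed = 1L) {
  if (collegeRate >= 0.5)
    stop("collegeRate must be below 0.5 so the education split stays 50/50")
  methods::new("SimulationConfig",
    nIndividuals = as.integer(nIndividuals), nSnps = as.integer(nSnps),
    mafRange = as.numeric(mafRange),
    nCausalEdu = as.integer(nCausalEdu), nCausalRes = as.integer(nCausalRes),
    h2Edu = h2Edu, h2Res = h2Res,
    ageRange = as.integer(ageRange), rtAgeSlope = rtAgeSlope, rtBase = rtBase,
    kappaEdu = kappaEdu, kappaRes = kappaRes,
    noiseSdRt = noiseSdRt, noiseSdEy = noiseSdEy, collegeRate = collegeRate,
    ldRho = ldRho, ldBlockSize = as.integer(ldBlockSize),
    posSpacing = as.integer(posSpacing),
    nCentres = as.integer(nCentres), seed = as.integer(seed))
}

# Non strand-ambiguous allele pairs used for simulated variants.
.allele_pairs <- matrix(c("A","C", "A","G", "C","A", "C","T",
                          "G","A", "G","T", "T","C", "T","G"),
                        ncol = 2L, byrow = TRUE)

#' Simulate a genotype panel
#'
#' Draws per-variant alternate-allele frequencies uniformly from
#' `mafRange` and genotypes as the sum of two haplotypes. With `ldRho = 0`
#' sites are independent binomial draws; with `ldRho > 0` each haplotype is a
#' latent Gaussian AR(1) within blocks of `ldBlockSize` adjacent variants,
#' thresholded at the allele frequency, giving block-wise LD with geometric
#' decay (used to exercise LD scores, clumping and conditional analysis).
#'
#' @param config A [SimulationConfig-class].
#' @param seed Seed (default: child seed derived from `config@seed`).
#' @return A [GenotypeData-class] with variants on chromosome 1, positions
#'   spaced `posSpacing` bp apart, non-strand-ambiguous alleles and INFO = 1.
#' @export
simulateGenotypes <- function(config, seed = childSeed(config@seed, "genotypes")) {
  methods::validObject(config)
  n <- config@nIndividuals
  m <- config@nSnps
  withSeed(seed, {
    freq <- runif(m, config@mafRange[1], config@mafRange[2])
    pairs <- .allele_pairs[sample.int(nrow(.allele_pairs), m, replace = TRUE), ,
                           drop = FALSE]
    if (config@ldRho == 0) {
      D <- matrix(rbinom(m * n, 2L, rep(freq, n)), nrow = m)
    } else {
      rho <- config@ldRho
      innov <- sqrt(1 - rho^2)
      thr <- qnorm(freq)
      i1 <- 1:n; i2 <- (n + 1L):(2L * n)
      Dt <- matrix(0L, nrow = n, ncol = m)  # column-major writes, then t()
      z <- rnorm(2L * n)
      Dt[, 1L] <- (z[i1] < thr[1L]) + (z[i2] < thr[1L])
      for (j in 2:m) {
        e <- rnorm(2L * n)
        if ((j - 1L) %% config@ldBlockSize == 0L) z <- e  # new block
        else z <- rho * z + innov * e
        Dt[, j] <- (z[i1] < thr[j]) + (z[i2] < thr[j])
      }
      D <- t(Dt)
    }
    ids <- sprintf("snp%05d", seq_len(m))
    GenotypeData(D, chrom = rep("1", m),
                 pos = seq_len(m) * config@posSpacing,
                 id = ids, ref = pairs[, 1L], alt = pairs[, 2L],
                 sampleIds = sprintf("I%06d", seq_len(n)))
  })
}

#' Simulate the two independent latent factors
#'
#' Builds per-individual scores of the education factor and the resilience
#' factor as `F = sum_j beta_j g_std_j + e`, with causal effects drawn
#' independently for the two factors (their genetic correlation is 0 by
#' construction). Effects and noise are rescaled so that the realised sample
#' genetic variance equals `h2` and the residual variance `1 - h2`, giving
#' unit-variance factors with the configured heritability.
#'
#' @param genotypes A [GenotypeData-class] from [simulateGenotypes()].
#' @param config The same [SimulationConfig-class].
#' @param seed Seed (default: derived child seed).
#' @return A list with elements `factors` (data.frame `IID, F_EDU, F_RES,
#'   G_EDU, G_RES`, where `G_*` are the true genetic values), `truth`
#'   (data.frame `SNP, BETA_E_TRUE, BETA_R_TRUE` of standardized true
#'   effects), and `realizedH2` (named numeric).
#' @export
simulateLatentFactors <- function(genotypes, config,
                                  seed = childSeed(config@seed, "factors")) {
  D <- dosages(genotypes)              # variants x samples
  m <- nrow(D); n <- ncol(D)
  mu <- rowMeans(D)
  sdg <- sqrt(pmax(rowSums((D - mu)^2) / (n - 1L), 0))
  sdg[sdg == 0] <- 1
  nc_e <- if (is.na(config@nCausalEdu)) m else config@nCausalEdu
  nc_r <- if (is.na(config@nCausalRes)) m else config@nCausalRes
  withSeed(seed, {
    draw <- function(nCausal, h2) {
      beta <- numeric(m)
      idx <- sample.int(m, nCausal)
      beta[idx] <- rnorm(nCausal)
      # genetic value on standardized dosages without materialising them
      g <- drop(crossprod(D, beta / sdg)) - sum(mu * beta / sdg)
      if (h2 == 0 || sd(g) == 0) {
        beta[] <- 0; g <- numeric(n)
      } else {
        scl <- sqrt(h2) / sd(g)
        beta <- beta * scl
        g <- (g - mean(g)) * scl
      }
      e <- rnorm(n)
      e <- (e - mean(e)) / sd(e) * sqrt(1 - h2)
      list(beta = beta, g = g, f = g + e)
    }
    edu <- draw(nc_e, config@h2Edu)
    res <- draw(nc_r, config@h2Res)
    list(
      factors = data.frame(IID = colnames(D),
                           F_EDU = edu$f, F_RES = res$f,
                           G_EDU = edu$g, G_RES = res$g,
                           stringsAsFactors = FALSE),
      truth = data.frame(SNP = snpIds(genotypes),
                         BETA_E_TRUE = edu$beta, BETA_R_TRUE = res$beta,
                         stringsAsFactors = FALSE),
      realizedH2 = c(edu = var(edu$g) / max(var(edu$f), .Machine$double.eps),
                     res = var(res$g) / max(var(res$f), .Machine$double.eps))
    )
  })
}

#' Simulate observed cohort phenotypes and covariates
#'
#' Maps the education factor monotonically onto years of education 14-20
#' (quantile thresholds; the top `collegeRate` quantile is flagged as
#' college, and mirrors the source cohort's recording by leaving their years
#' missing), and generates reaction time as
#' `rtBase + rtAgeSlope * (age - mean age) - kappaEdu * F_EDU -
#' kappaRes * F_RES + nuisance + noise`, so higher factor scores mean faster
#' responses. Sex, assessment centre, genotyping array and eight principal
#' components are generated as nuisance covariates with small effects.
#'
#' @param factors Output of [simulateLatentFactors()].
#' @param genotypes The matching [GenotypeData-class].
#' @param config The [SimulationConfig-class].
#' @param seed Seed (default: derived child seed).
#' @return A data.frame with columns `IID, SEX, AGE, CENTRE, ARRAY, PC1..PC8,
#'   EDU_YEARS, COLLEGE, RT_MS`.
#' @export
simulateCohortPhenotypes <- function(factors, genotypes, config,
                                     seed = childSeed(config@seed, "phenotypes")) {
  fs <- factors$factors
  n <- nrow(fs)
  withSeed(seed, {
    age <- sample(config@ageRange[1]:config@ageRange[2], n, replace = TRUE)
    sex <- rbinom(n, 1L, 0.5)
    centre <- sample.int(config@nCentres, n, replace = TRUE)
    array <- rbinom(n, 1L, 0.1)
    pcs <- matrix(rnorm(n * 8L), n, 8L,
                  dimnames = list(NULL, paste0("PC", 1:8)))
    centreEff <- rnorm(config@nCentres, 0, 5)

    liab <- fs$F_EDU + 0.02 * pcs[, 1L]
    if (config@noiseSdEy > 0) liab <- liab + rnorm(n, 0, config@noiseSdEy)
    cr <- config@collegeRate
    qs <- rank(liab, ties.method = "first") / n
    breaks <- c(0, 0.125, 0.25, 0.375, 0.5,
                0.5 + (0.5 - cr) / 2, 1 - cr, 1)
    years <- c(14:20)[findInterval(qs, breaks, rightmost.closed = TRUE,
                                   left.open = TRUE)]
    college <- as.integer(years == 20L)
    eduYears <- ifelse(college == 1L, NA_integer_, years)

    rt <- config@rtBase +
      config@rtAgeSlope * (age - mean(age)) -
      config@kappaEdu * fs$F_EDU -
      config@kappaRes * fs$F_RES +
      10 * sex + centreEff[centre] + 2 * pcs[, 1L] +
      rnorm(n, 0, config@noiseSdRt)

    out <- data.frame(IID = fs$IID, SEX = sex, AGE = age, CENTRE = centre,
                      ARRAY = array, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(pcs))
    out$EDU_YEARS <- eduYears
    out$COLLEGE <- college
    out$RT_MS <- rt
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulateGenotypes()],
#' [simulateLatentFactors()] and [simulateCohortPhenotypes()] with child
#' seeds derived from the master seed in `config`.
#'
#' @param config A [SimulationConfig-class].
#' @return A list: `genotypes`, `cohort`, `factors`, `truth`, `realizedH2`.
#' @export
simulateCohort <- function(config) {
  genotypes <- simulateGenotypes(config)
  fac <- simulateLatentFactors(genotypes, config)
  cohort <- simulateCohortPhenotypes(fac, genotypes, config)
  list(genotypes = genotypes, cohort = cohort, factors = fac$factors,
       truth = fac$truth, realizedH2 = fac$realizedH2)
}
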