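makeGcov <- function(S, V = diag(3) * 1e-4) {
  new("GeneticCovariance", S = S, V = V,
      intercepts = c(t1 = 1, t2 = 1, cross = 0), M = 1000, nBlocks = 200L,
      traits = c("EY+Res", "EY/NonRes"), rg = S[1, 2] / sqrt(S[1, 1] * S[2, 2]),
      rgSE = 0.1, rgP = 0.5, h2SE = c(0.01, 0.01))
}

mungedFromB <- function(b, N, freq, snp = sprintf("rs%d", seq_along(b))) {
  # standardized effect b corresponds to Z = b * sqrt(N * 2pq)
  data.frame(SNP = snp, A1 = "G", A2 = "A",
             Z = b * sqrt(N * 2 * freq * (1 - freq)), N = N,
             stringsAsFactors = FALSE)
}

freqRefFor <- function(snp, freq) {
  data.frame(SNP = snp, A1 = "G", A2 = "A", FRQ = freq, CHR = "1",
             BP = seq_along(snp) * 1000L, stringsAsFactors = FALSE)
}

test_that("Cholesky loadings in closed form match the hand-derived cases", {
  l <- pathLoadings(fitCholesky(makeGcov(diag(2))))
  expect_equal(unname(l), c(0, 1, 1))
  l2 <- pathLoadings(fitCholesky(makeGcov(matrix(c(1, .5, .5, 1), 2))))
  expect_equal(unname(l2), c(0.5, 1, sqrt(0.75)), tolerance = 1e-12)
  expect_error(fitCholesky(makeGcov(matrix(c(1, 0, 0, 0), 2))), "S22")
  expect_error(fitCholesky(makeGcov(matrix(c(.1, .5, .5, 1), 2))),
               "inadmissible")
})

test_that("closed-form loadings agree with the numerical WLS oracle", {
  set.seed(22)
  for (i in 1:25) {
    a <- matrix(rnorm(4, sd = 0.5), 2)
    S <- crossprod(a) + diag(2) * 0.2
    l <- pathLoadings(fitCholesky(makeGcov(S)))
    o <- wlsCholeskyOracle(S)
    expect_lt(max(abs(unname(l) - unname(o))), 1e-6)
  }
})

test_that("loading sampling covariance follows the delta method", {
  S <- matrix(c(0.25, 0.10, 0.10, 0.18), 2)
  V <- matrix(c(4, 1, 0.5, 1, 3, 0.8, 0.5, 0.8, 2) * 1e-4, 3)
  V <- (V + t(V)) / 2
  ld <- fitCholesky(makeGcov(S, V))
  # numerical Jacobian cross-check
  f <- function(s) {
    c(s[2] / sqrt(s[3]), sqrt(s[3]), sqrt(s[1] - s[2]^2 / s[3]))
  }
  s0 <- c(S[1, 1], S[1, 2], S[2, 2])
  J <- sapply(1:3, function(k) {
    h <- 1e-7
    sp <- s0; sp[k] <- sp[k] + h
    sm <- s0; sm[k] <- sm[k] - h
    (f(sp) - f(sm)) / (2 * h)
  })
  expect_equal(unname(ld@vcov), unname(J %*% V %*% t(J)), tolerance = 1e-5)
})

test_that("per-SNP subtraction matches hand algebra and the WLS oracle", {
  lam <- fitCholesky(makeGcov(matrix(c(1, .5, .5, 1), 2)))
  freq <- 0.25
  N <- 50000
  e1 <- mungedFromB(0.02, N, freq, "rs1")
  e2 <- mungedFromB(0.01, N, freq, "rs1")
  out <- gwasBySubtraction(e1, e2, lam, freqRefFor("rs1", freq))
  edu <- as.data.frame(eduYearsStats(out))
  res <- as.data.frame(resilienceStats(out))
  expect_equal(edu$BETA, 0.01, tolerance = 1e-10)
  expect_equal(res$BETA, (0.02 - 0.5 * 0.01) / sqrt(0.75), tolerance = 1e-10)
  o <- wlsSnpOracle(0.02, 0.01, 0.5, 1, sqrt(0.75))
  expect_equal(edu$BETA, unname(o["betaEdu"]), tolerance = 1e-10)
  expect_equal(res$BETA, unname(o["betaRes"]), tolerance = 1e-10)
})

test_that("a SNP acting purely through EduYears has zero Resilience effect", {
  lam <- fitCholesky(makeGcov(matrix(c(0.3, 0.12, 0.12, 0.2), 2)))
  ll <- pathLoadings(lam)
  x <- 0.015
  freq <- 0.3
  e1 <- mungedFromB(ll["lambdaEduEyres"] * x, 40000, freq, "rs1")
  e2 <- mungedFromB(ll["lambdaEduNonres"] * x, 40000, freq, "rs1")
  # (the zero-beta latent trait makes effective N undefined: warned, NA)
  expect_warning(out <- gwasBySubtraction(e1, e2, lam,
                                          freqRefFor("rs1", freq)),
                 "effective N undefined")
  expect_equal(as.data.frame(resilienceStats(out))$BETA, 0, tolerance = 1e-12)
  expect_equal(as.data.frame(eduYearsStats(out))$BETA, x, tolerance = 1e-12)
  # and with no EY/NonRes signal, everything loads on Resilience
  e0 <- mungedFromB(0, 40000, freq, "rs1")
  expect_warning(out2 <- gwasBySubtraction(e1, e0, lam,
                                           freqRefFor("rs1", freq)),
                 "effective N undefined")
  expect_equal(as.data.frame(eduYearsStats(out2))$BETA, 0)
  expect_equal(as.data.frame(resilienceStats(out2))$BETA,
               unname(ll["lambdaEduEyres"] * x / ll["lambdaResEyres"]),
               tolerance = 1e-12)
})

test_that("reconstruction identity holds per variant to 1e-10", {
  set.seed(23)
  lam <- fitCholesky(makeGcov(matrix(c(0.25, 0.1, 0.1, 0.18), 2)))
  ll <- pathLoadings(lam)
  M <- 100
  freq <- runif(M, 0.12, 0.38)
  b1 <- rnorm(M, 0, 0.01)
  b2 <- rnorm(M, 0, 0.01)
  snp <- sprintf("rs%d", 1:M)
  out <- gwasBySubtraction(mungedFromB(b1, 30000, freq, snp),
                           mungedFromB(b2, 30000, freq, snp),
                           lam, freqRefFor(snp, freq))
  bEdu <- as.data.frame(eduYearsStats(out))$BETA
  bRes <- as.data.frame(resilienceStats(out))$BETA
  expect_lt(max(abs(ll["lambdaEduEyres"] * bEdu +
                    ll["lambdaResEyres"] * bRes - b1)), 1e-10)
  expect_lt(max(abs(ll["lambdaEduNonres"] * bEdu - b2)), 1e-10)
  # oracle equivalence on every variant
  for (j in seq_len(10)) {
    o <- wlsSnpOracle(b1[j], b2[j], ll[1], ll[2], ll[3])
    expect_equal(bEdu[j], unname(o["betaEdu"]), tolerance = 1e-8)
    expect_equal(bRes[j], unname(o["betaRes"]), tolerance = 1e-8)
  }
})

test_that("negating all input Z negates latent effects, Neff unchanged", {
  set.seed(24)
  lam <- fitCholesky(makeGcov(matrix(c(0.25, 0.1, 0.1, 0.18), 2)))
  M <- 50
  freq <- runif(M, 0.15, 0.35)
  snp <- sprintf("rs%d", 1:M)
  m1 <- mungedFromB(rnorm(M, 0, 0.01), 30000, freq, snp)
  m2 <- mungedFromB(rnorm(M, 0, 0.01), 30000, freq, snp)
  ref <- freqRefFor(snp, freq)
  a <- gwasBySubtraction(m1, m2, lam, ref)
  m1n <- transform(m1, Z = -Z); m2n <- transform(m2, Z = -Z)
  b <- gwasBySubtraction(m1n, m2n, lam, ref)
  expect_equal(as.data.frame(resilienceStats(b))$BETA,
               -as.data.frame(resilienceStats(a))$BETA)
  expect_equal(as.data.frame(eduYearsStats(b))$BETA,
               -as.data.frame(eduYearsStats(a))$BETA)
  expect_equal(effectiveSampleSizes(b), effectiveSampleSizes(a))
})

test_that("propagating loading uncertainty widens the per-SNP SEs", {
  S <- matrix(c(0.25, 0.1, 0.1, 0.18), 2)
  V <- diag(3) * 1e-3
  lam <- fitCholesky(makeGcov(S, V))
  freq <- 0.3
  m1 <- mungedFromB(0.02, 30000, freq, "rs1")
  m2 <- mungedFromB(0.012, 30000, freq, "rs1")
  ref <- freqRefFor("rs1", freq)
  fixed <- gwasBySubtraction(m1, m2, lam, ref)
  prop <- gwasBySubtraction(m1, m2, lam, ref,
                            includeLoadingUncertainty = TRUE)
  expect_gt(as.data.frame(resilienceStats(prop))$SE,
            as.data.frame(resilienceStats(fixed))$SE)
  expect_gt(as.data.frame(eduYearsStats(prop))$SE,
            as.data.frame(eduYearsStats(fixed))$SE)
})

test_that("effective N inverts the standardization and applies the MAF trim", {
  # hand-computed single variant: (Z/beta)^2 / (2 maf (1-maf))
  one <- data.frame(FRQ = 0.25, BETA = 0.02, Z = 5)
  expect_equal(effectiveN(one), 250^2 / 0.375, tolerance = 1e-12)
  # variants outside (0.10, 0.40) are trimmed
  d <- data.frame(FRQ = c(0.25, 0.05, 0.45), BETA = rep(0.02, 3),
                  Z = c(5, 50, 50))
  expect_equal(effectiveN(d), 250^2 / 0.375)
  expect_error(effectiveN(data.frame(FRQ = 0.05, BETA = 0.1, Z = 1)),
               "MAF trim")
  # exact inversion: Z = beta * sqrt(N * 2pq) for every variant gives N
  set.seed(25)
  freq <- runif(200, 0.11, 0.39)
  beta <- rnorm(200, 0, 0.02)
  N <- 111316
  d2 <- data.frame(FRQ = freq, BETA = beta,
                   Z = beta * sqrt(N * 2 * freq * (1 - freq)))
  expect_equal(effectiveN(d2), N, tolerance = 1e-9)
})
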