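test_that("LD scores: self term, perfect LD, and window exclusion", {
  set.seed(14)
  d <- rbinom(200, 2, 0.4)
  # three isolated variants (outside each other's window)
  gIso <- makeGenotypes(rbind(d, rbinom(200, 2, 0.3), rbinom(200, 2, 0.2)),
                        pos = c(1L, 3000000L, 6000000L))
  l2 <- computeLDScores(gIso, windowKb = 1000)$L2
  expect_equal(l2, rep(1, 3))
  # duplicated variant in the window: r2 = 1, adjusted r2 = 1, l2 = 2
  gDup <- makeGenotypes(rbind(d, d), pos = c(1000L, 2000L))
  expect_equal(computeLDScores(gDup)$L2, c(2, 2), tolerance = 1e-12)
  expect_error(computeLDScores(makeGenotypes(rbind(c(0, 1), c(1, 2)))),
               "more than 2")
})

test_that("adjusted r2 is unbiased: independent variants have mean l2 near 1", {
  set.seed(15)
  n <- 1000
  D <- matrix(rbinom(100 * n, 2, 0.3), nrow = 100)
  g <- makeGenotypes(D, pos = seq_len(100) * 1000L)
  l2 <- computeLDScores(g)$L2
  # each l2 sums 99 adjusted r2 terms with null mean 0 and variance ~ 2/n^2
  expect_lt(abs(mean(l2) - 1), 3 * sqrt(2 * 99) / n)
})

test_that("munging aligns alleles, drops ambiguous sites and filters", {
  ref <- data.frame(SNP = sprintf("rs%d", 1:10),
                    A1 = c(rep("G", 8), "T", "C"),
                    A2 = c(rep("A", 8), "A", "G"),
                    stringsAsFactors = FALSE)
  ss <- data.frame(SNP = sprintf("rs%d", 1:10),
                   A1 = c("G", "A", rep("G", 6), "T", "C"),
                   A2 = c("A", "G", rep("A", 6), "A", "G"),
                   Z = c(2, 2, rep(1, 6), 1, 1),
                   N = 5000,
                   FRQ = c(rep(0.3, 5), 0.005, rep(0.3, 4)),
                   stringsAsFactors = FALSE)
  out <- mungeSumstats(ss, ref, minMaf = 0.01)
  # rs9 is T/A and rs10 is C/G (strand-ambiguous): removed
  # rs6 fails the MAF filter; rs2 is swapped relative to the reference
  expect_equal(nrow(out), 7)
  expect_false(any(c("rs9", "rs10", "rs6") %in% out$SNP))
  expect_equal(out$Z[out$SNP == "rs2"], -2)
  expect_equal(out$FRQ[out$SNP == "rs2"], 0.7)
  expect_equal(out$A1[out$SNP == "rs2"], "G")
  expect_error(mungeSumstats(transform(ss, SNP = paste0("x", SNP)), ref),
               "no variants overlap")
})

test_that("an exact linear chi-square relation is recovered to 1e-8", {
  set.seed(16)
  M <- 500
  l2 <- runif(M, 1, 8)
  N <- 20000
  h2 <- 0.4
  chi2 <- 1 + N * l2 / M * h2
  munged <- data.frame(SNP = sprintf("rs%d", 1:M), A1 = "G", A2 = "A",
                       Z = sqrt(chi2), N = N)
  ld <- data.frame(SNP = munged$SNP, CHR = "1", BP = seq_len(M) * 1000L,
                   L2 = l2)
  suppressMessages(fit <- ldscH2(munged, ld, M = M))
  expect_equal(fit$h2, h2, tolerance = 1e-8)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  # scale equivariance: multiplying Z by c scales the slope by c^2
  munged2 <- transform(munged, Z = 2 * Z)
  suppressMessages(fit2 <- ldscH2(munged2, ld, M = M))
  expect_equal(fit2$h2, 4 * h2, tolerance = 1e-7)
  expect_equal(fit2$intercept, 4, tolerance = 1e-7)
})

test_that("a null trait has h2 near 0 and intercept near 1", {
  set.seed(17)
  M <- 2000
  l2 <- runif(M, 1, 10)
  munged <- data.frame(SNP = sprintf("rs%d", 1:M), A1 = "G", A2 = "A",
                       Z = rnorm(M), N = 50000)
  ld <- data.frame(SNP = munged$SNP, CHR = "1", BP = seq_len(M) * 1000L,
                   L2 = l2)
  fit <- ldscH2(munged, ld, M = M)
  expect_lt(abs(fit$h2) / fit$h2SE, 2)
  expect_lt(abs(fit$intercept - 1) / fit$interceptSE, 2)
})

test_that("heritability of a simulated quantitative trait is recovered", {
  cfg <- simulationConfig(nIndividuals = 6000L, nSnps = 1000L, h2Edu = 0.5,
                          seed = 18L, ldRho = 0.9, ldBlockSize = 25L,
                          mafRange = c(0.1, 0.5))
  g <- simulateGenotypes(cfg)
  fac <- simulateLatentFactors(g, cfg)
  ss <- runGWAS(g, fac$factors$F_EDU, model = "linear")
  m <- mungeSumstats(ss, g)
  ld <- computeLDScores(g)
  fit <- ldscH2(m, ld)
  expect_lt(abs(fit$h2 - 0.5) / fit$h2SE, 2)
})

test_that("bivariate LDSC: self-correlation is exactly 1, V matches the SEs", {
  set.seed(19)
  M <- 800
  l2 <- runif(M, 1, 6)
  z <- rnorm(M, sd = sqrt(1 + 30000 * l2 / M * 0.3))
  munged <- data.frame(SNP = sprintf("rs%d", 1:M), A1 = "G", A2 = "A",
                       Z = z, N = 30000)
  ld <- data.frame(SNP = munged$SNP, CHR = "1", BP = seq_len(M) * 1000L,
                   L2 = l2)
  suppressMessages(gc <- ldscRG(munged, munged, ld, M = M))
  expect_equal(gc@rg, 1, tolerance = 1e-12)
  S <- geneticCovariance(gc)
  expect_equal(S[1, 1], S[1, 2], tolerance = 1e-12)
  V <- samplingCovariance(gc)
  expect_equal(unname(gc@h2SE), unname(sqrt(c(V[1, 1], V[3, 3]))))
  expect_equal(V, t(V))
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-12))
})

test_that("genetic correlation of simulated trait pairs is recovered", {
  cfg <- simulationConfig(nIndividuals = 5000L, nSnps = 800L, seed = 20L,
                          ldRho = 0.9, ldBlockSize = 20L,
                          mafRange = c(0.1, 0.5))
  g <- simulateGenotypes(cfg)
  D <- dosages(g)
  n <- ncol(D)
  sdg <- sqrt(apply(D, 1, var))
  gval <- function(b) {
    v <- drop(crossprod(D, b / sdg))
    (v - mean(v)) / sd(v)
  }
  ld <- computeLDScores(g)
  # three independent trait-pair replicates per true rg; the pooled
  # (inverse-variance-weighted) estimate must sit within 2 pooled SEs
  for (rhoTrue in c(0, 0.5)) {
    dev <- se <- numeric(0)
    for (rep in 21:23) {
      set.seed(rep)
      shared <- gval(rnorm(800)); u1 <- gval(rnorm(800)); u2 <- gval(rnorm(800))
      trait <- function(gunique) {
        gg <- sqrt(rhoTrue) * shared + sqrt(1 - rhoTrue) * gunique
        gg <- sqrt(0.4) * gg / sd(gg)
        gg + rnorm(n, 0, sqrt(0.6))
      }
      m1 <- mungeSumstats(runGWAS(g, trait(u1), model = "linear"), g)
      m2 <- mungeSumstats(runGWAS(g, trait(u2), model = "linear"), g)
      # jackknife blocks kept wider than the panel's 20-variant LD blocks
      gc <- suppressMessages(ldscRG(m1, m2, ld, nBlocks = 20L))
      dev <- c(dev, gc@rg - rhoTrue)
      se <- c(se, gc@rgSE)
    }
    w <- 1 / se^2
    pooledZ <- abs(sum(w * dev) / sum(w)) * sqrt(sum(w))
    expect_lt(pooledZ, 2, label = paste("pooled rg recovery at rg =", rhoTrue))
  }
})

test_that("jackknife block count is reduced for small panels", {
  munged <- data.frame(SNP = sprintf("rs%d", 1:50), A1 = "G", A2 = "A",
                       Z = rnorm(50), N = 1000)
  ld <- data.frame(SNP = munged$SNP, CHR = "1", BP = 1:50 * 1000L,
                   L2 = runif(50, 1, 3))
  expect_message(fit <- ldscH2(munged, ld), "reducing jackknife blocks")
  expect_lte(fit$nBlocks, 25)
})
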