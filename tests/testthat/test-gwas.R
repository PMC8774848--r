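test_that("exact Hardy-Weinberg test matches the direct-enumeration oracle", {
  cases <- list(c(0, 10, 90), c(25, 50, 25), c(3, 1, 96), c(500, 200, 300),
                c(0, 100, 0), c(10, 0, 10), c(1, 2, 3), c(0, 0, 50))
  for (cc in cases) {
    expect_equal(hweExactTest(cc[1], cc[2], cc[3]),
                 hweOracle(cc[1], cc[2], cc[3]),
                 tolerance = 1e-10,
                 info = paste(cc, collapse = "/"))
  }
})

test_that("variant QC applies each filter and removes duplicates", {
  n <- 10000
  clean <- c(rep(0, 2500), rep(1, 5000), rep(2, 2500))
  dup <- clean
  mafFail <- c(rep(1, 10), rep(0, n - 10))
  hweFail <- c(rep(2, 3000), rep(0, 7000))
  genoFail <- c(rep(NA, 500), rep(0, 2375), rep(1, 4750), rep(2, 2375))
  D <- rbind(clean, dup, mafFail, hweFail, genoFail)
  g <- makeGenotypes(D, pos = c(1000L, 1000L, 3000L, 4000L, 5000L),
                     id = paste0("v", 1:5))
  out <- variantQC(g)
  expect_equal(out$report[c("geno", "maf", "info", "hwe", "dup")],
               c(geno = 1, maf = 1, info = 0, hwe = 1, dup = 1))
  expect_equal(out$report[["retained"]], 1)
  expect_equal(snpIds(out$genotypes), "v1")
  # vacuous thresholds remove only duplicates
  out2 <- variantQC(g, qcThresholds(geno = 1, maf = 0, info = 0, hwe = 0))
  expect_equal(out2$report[["removed"]], 1)
  # all-pass input returns identical genotypes
  g3 <- makeGenotypes(rbind(clean, rev(clean)), pos = c(1000L, 2000L),
                      id = c("a", "b"))
  out3 <- variantQC(g3)
  expect_equal(out3$report[["removed"]], 0)
  expect_identical(dosages(out3$genotypes), dosages(g3))
  # removing everything is an error
  expect_error(variantQC(makeGenotypes(rbind(mafFail), id = "m")),
               "every variant")
})

test_that("no-covariate logistic beta equals the 2x2 log odds ratio", {
  g <- makeGenotypes(rbind(c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60))),
                     id = "rs1")
  y <- c(rep(1, 100), rep(0, 100))
  ss <- as.data.frame(runGWAS(g, y, model = "logistic"))
  expect_equal(ss$BETA, log(2.25), tolerance = 1e-6)
  expect_equal(ss$Z, ss$BETA / ss$SE)
  expect_equal(ss$P, 2 * pnorm(-abs(ss$Z)))
  expect_equal(ss$N, 200)
})

test_that("logistic and linear fits agree with glm/lm including SEs", {
  set.seed(8)
  n <- 400
  D <- rbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.45))
  C <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  g <- makeGenotypes(D, id = c("rs1", "rs2"))
  yb <- rbinom(n, 1, plogis(-0.2 + 0.4 * D[1, ] + 0.3 * C[, 1]))
  ss <- as.data.frame(runGWAS(g, yb, covariates = C, model = "logistic"))
  for (j in 1:2) {
    fit <- glm(yb ~ D[j, ] + C, family = binomial())
    expect_equal(ss$BETA[j], unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(ss$SE[j], unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-6)
  }
  yq <- 1 + 0.3 * D[2, ] + 0.5 * C[, 2] + rnorm(n)
  sq <- as.data.frame(runGWAS(g, yq, covariates = C, model = "linear"))
  for (j in 1:2) {
    fit <- lm(yq ~ D[j, ] + C)
    expect_equal(sq$BETA[j], unname(coef(fit)[2]), tolerance = 1e-8)
    expect_equal(sq$SE[j], unname(summary(fit)$coefficients[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("swapping alleles and reflecting dosage negates beta and Z only", {
  set.seed(9)
  n <- 300
  d <- rbinom(n, 2, 0.35)
  y <- rbinom(n, 1, plogis(0.5 * d - 0.3))
  g1 <- makeGenotypes(rbind(d), id = "rs1", ref = "A", alt = "G")
  g2 <- makeGenotypes(rbind(2 - d), id = "rs1", ref = "G", alt = "A")
  s1 <- as.data.frame(runGWAS(g1, y))
  s2 <- as.data.frame(runGWAS(g2, y))
  expect_equal(s2$BETA, -s1$BETA, tolerance = 1e-8)
  expect_equal(s2$Z, -s1$Z, tolerance = 1e-8)
  expect_equal(s2$P, s1$P, tolerance = 1e-10)
  expect_equal(s2$FRQ, 1 - s1$FRQ)
})

test_that("perfect separation and collinear conditioning are flagged", {
  set.seed(10)
  d <- c(rep(0, 25), rep(1, 15), rep(2, 10))
  g <- makeGenotypes(rbind(d, rbinom(50, 2, 0.4)), id = c("rs1", "rs2"))
  ySep <- as.integer(d > 0)
  ss <- as.data.frame(runGWAS(g, ySep, model = "logistic"))
  expect_equal(ss$FLAG[1], "nonconverged")
  expect_true(is.na(ss$BETA[1]))
  # conditioning a variant on itself is collinear
  y <- rbinom(50, 1, 0.5)
  sc <- as.data.frame(runGWAS(g, y, conditionSnp = "rs1"))
  expect_equal(sc$FLAG[1], "collinear")
  expect_true(is.na(sc$BETA[1]))
})

test_that("conditioning on the causal index SNP weakens an LD partner", {
  set.seed(11)
  n <- 3000
  g1 <- rbinom(n, 2, 0.3)
  g2 <- g1
  redraw <- sample.int(n, n %/% 10)
  g2[redraw] <- rbinom(length(redraw), 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.2 + 0.6 * g1))
  g <- makeGenotypes(rbind(g1, g2), id = c("idx", "partner"))
  pMarg <- as.data.frame(runGWAS(g, y))$P[2]
  pCond <- as.data.frame(runGWAS(g, y, conditionSnp = "idx"))$P[2]
  expect_lt(pMarg, 1e-10)
  expect_gt(pCond, pMarg)
})

test_that("Bonferroni thresholds reproduce the published corrections", {
  expect_equal(signif(bonferroniThreshold(0.05, 18879), 4), 2.648e-6)
  expect_equal(bonferroniThreshold(0.05, 10), 0.005)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_error(bonferroniThreshold(0.05, 0), "m must be")
  expect_error(bonferroniThreshold(1.5, 10), "alpha")
})

test_that("replication sign test gives exact binomial tail probabilities", {
  mkLeads <- function(beta, snp = sprintf("rs%d", seq_along(beta))) {
    data.frame(SNP = snp, A1 = "G", A2 = "A", BETA = beta,
               P = rep(1e-9, length(beta)), stringsAsFactors = FALSE)
  }
  d <- mkLeads(rep(0.1, 10))
  rSame <- mkLeads(rep(0.05, 10)); rSame$P <- rep(0.001, 10)
  out <- signTestReplication(d, rSame)
  expect_equal(out$nConcordant, 10)
  expect_equal(out$p, 2^-10)
  expect_equal(signif(out$p, 3), 9.77e-4)
  expect_equal(out$bonferroni, 0.005)
  expect_true(all(out$perSnp$SIG_BONFERRONI))

  rMix <- mkLeads(c(rep(0.05, 8), rep(-0.05, 2)))
  expect_equal(signTestReplication(d, rMix)$p, 56 / 1024)

  expect_equal(signTestReplication(mkLeads(0.2), mkLeads(0.1))$p, 0.5)

  # allele swap in replication is harmonised before comparing signs
  rSwap <- mkLeads(rep(-0.05, 10))
  rSwap$A1 <- "A"; rSwap$A2 <- "G"
  expect_equal(signTestReplication(d, rSwap)$nConcordant, 10)

  # leads absent from replication reduce n with a warning
  rShort <- mkLeads(rep(0.05, 8))
  expect_warning(out2 <- signTestReplication(d, rShort), "absent")
  expect_equal(out2$nTested, 8)
})
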