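# Independent oracles and fixture builders shared across test files.

# Exact Hardy-Weinberg p-value by direct evaluation of the conditional
# distribution of heterozygote counts (log-factorial formula), independent of
# the package's recurrence implementation.
hweOracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nB <- 2 * nBB + nAB
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  lp <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- (nB - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(nAB, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Numerical weighted-least-squares fit of the no-SNP Cholesky model:
# minimise the discrepancy between implied and observed unique elements of S.
# The model is just-identified, so the minimiser reproduces S exactly.
wlsCholeskyOracle <- function(S, W = diag(3)) {
  obs <- c(S[1, 1], S[1, 2], S[2, 2])
  fn <- function(par) {
    lee <- par[1]; len <- par[2]; lre <- par[3]
    imp <- c(lee^2 + lre^2, lee * len, len^2)
    d <- imp - obs
    drop(t(d) %*% W %*% d)
  }
  best <- NULL
  for (st in list(c(0.3, 0.7, 0.7), c(0.1, 1, 1), c(0.8, 0.5, 0.3))) {
    o <- optim(st, fn, method = "BFGS",
               control = list(reltol = 1e-16, maxit = 2000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # Gauss-Newton polish so the minimiser is tight enough to compare at 1e-6
  # absolute precision (the model is just-identified: residuals reach 0)
  par <- best$par
  for (it in 1:100) {
    r <- c(par[1]^2 + par[3]^2, par[1] * par[2], par[2]^2) - obs
    J <- rbind(c(2 * par[1], 0, 2 * par[3]),
               c(par[2], par[1], 0),
               c(0, 2 * par[2], 0))
    step <- tryCatch(qr.solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    par <- par - step
    if (max(abs(step)) < 1e-14) break
  }
  # sign convention: lambdaEduNonres >= 0, lambdaResEyres >= 0
  if (par[2] < 0) par[1:2] <- -par[1:2]
  par[3] <- abs(par[3])
  names(par) <- c("lambdaEduEyres", "lambdaEduNonres", "lambdaResEyres")
  par
}

# Numerical least-squares solution of the per-SNP path system given observed
# standardized effects (b1 on EY+Res, b2 on EY/NonRes): solve the linear
# model (b1, b2) = A (betaEdu, betaRes) by QR, independent of the closed form.
wlsSnpOracle <- function(b1, b2, lee, len, lre) {
  A <- rbind(c(unname(lee), unname(lre)), c(unname(len), 0))
  sol <- unname(qr.solve(A, c(unname(b1), unname(b2))))
  c(betaEdu = sol[1], betaRes = sol[2])
}

# Tiny GenotypeData built from an explicit dosage matrix (variants x samples).
makeGenotypes <- function(D, pos = seq_len(nrow(D)) * 1000L, chrom = "1",
                          ref = rep("A", nrow(D)), alt = rep("G", nrow(D)),
                          id = sprintf("rs%03d", seq_len(nrow(D))),
                          info = rep(1, nrow(D))) {
  GenotypeData(D, chrom = rep(chrom, length.out = nrow(D)), pos = pos,
               id = id, ref = ref, alt = alt, info = info)
}

# Pair of dosage vectors with an exactly chosen squared correlation, built
# from an orthonormal mean-zero basis and shifted into [0, 2].
dosagePairWithR2 <- function(r2, n = 8) {
  stopifnot(n %% 4 == 0)
  u <- rep(c(1, -1), n / 2)
  v <- rep(c(1, 1, -1, -1), n / 4)
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  y <- sqrt(r2) * u + sqrt(1 - r2) * v
  rbind(1 + 0.9 * u / max(abs(u)), 1 + 0.9 * y / max(abs(y)))
}

# Minimal sumstats data.frame for locus tests (only the columns the locus
# tools consult).
makeSumstats <- function(snp, chr, bp, p, beta = rep(0.1, length(snp)),
                         frq = rep(0.3, length(snp))) {
  data.frame(SNP = snp, CHR = as.character(chr), BP = bp,
             A1 = "G", A2 = "A", FRQ = frq, BETA = beta,
             SE = abs(beta) / abs(qnorm(p / 2)), Z = qnorm(p / 2) * -sign(beta),
             P = p, N = 1000, stringsAsFactors = FALSE)
}
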