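#' Compute LD scores from a reference panel
#'
#' For each variant j, `l2_j = 1 + sum_k adj_r2_jk` over all other variants k
#' within `windowKb` of j on the same chromosome, where
#' `adj_r2 = r2 - (1 - r2) / (n - 2)` is the usual bias-adjusted squared
#' correlation (its expectation is 0 for unlinked variants) and the self term
#' contributes exactly 1.
#'
#' @param genotypes A [GenotypeData-class] reference panel (n > 2 samples).
#' @param windowKb Window half-width in kb (default 1000).
#' @return A data.frame `SNP, CHR, BP, L2`.
#' @export
computeLDScores <- function(genotypes, windowKb = 1000) {
  D <- dosages(genotypes)
  vi <- variantInfo(genotypes)
  n <- ncol(D)
  if (n <= 2L) stop("LD scores require more than 2 reference samples")
  w <- windowKb * 1000
  l2 <- numeric(nrow(D))
  for (chr in unique(vi$CHR)) {
    sel <- which(vi$CHR == chr)
    ord <- sel[order(vi$BP[sel])]
    pos <- vi$BP[ord]
    X <- standardizeColumns(t(D[ord, , drop = FALSE]))
    mc <- length(ord)
    chunk <- 512L
    for (a in seq(1L, mc, by = chunk)) {
      b <- min(a + chunk - 1L, mc)
      lo <- findInterval(pos[a] - w, pos) + 1L
      hi <- findInterval(pos[b] + w, pos)
      R <- crossprod(X[, a:b, drop = FALSE],
                     X[, lo:hi, drop = FALSE]) / (n - 1L)
      r2 <- R^2
      adj <- r2 - (1 - r2) / (n - 2L)
      for (jj in seq_len(b - a + 1L)) {
        j <- a + jj - 1L
        inWin <- abs(pos[lo:hi] - pos[j]) <= w
        inWin[j - lo + 1L] <- FALSE  # self term added separately
        l2[ord[j]] <- 1 + sum(adj[jj, inWin])
      }
    }
  }
  data.frame(SNP = vi$SNP, CHR = vi$CHR, BP = vi$BP, L2 = l2,
             stringsAsFactors = FALSE)
}

#' Harmonise summary statistics against a reference ("munging")
#'
#' Intersects a summary-statistics table with a reference allele table,
#' removes strand-ambiguous (A/T, C/G) variants, aligns effect alleles to the
#' reference (negating Z on an A1/A2 swap, dropping allele mismatches), and
#' applies MAF and INFO filters.
#'
#' @param sumstats A [SumStats-class] or data.frame with `SNP, A1, A2, N` and
#'   `Z` (or `BETA` and `SE`, from which Z is formed).
#' @param reference A [GenotypeData-class], or a data.frame with
#'   `SNP, A1, A2` giving the reference effect/other alleles.
#' @param minMaf Minimum minor allele frequency (needs a `FRQ` column;
#'   default 0.01).
#' @param minInfo Minimum INFO (applied when an `INFO` column is present;
#'   default 0.9).
#' @return A data.frame `SNP, A1, A2, Z, N` (plus `FRQ` when available),
#'   with an attribute `counts` recording how many variants each step
#'   removed.
#' @export
mungeSumstats <- function(sumstats, reference, minMaf = 0.01, minInfo = 0.9) {
  ss <- as.data.frame(sumstats)
  if (!"Z" %in% names(ss)) {
    stopifnot(all(c("BETA", "SE") %in% names(ss)))
    ss$Z <- ss$BETA / ss$SE
  }
  if (methods::is(reference, "GenotypeData")) {
    vi <- variantInfo(reference)
    ref <- data.frame(SNP = vi$SNP, A1 = vi$ALT, A2 = vi$REF,
                      stringsAsFactors = FALSE)
  } else {
    ref <- as.data.frame(reference)
  }
  counts <- c(input = nrow(ss))

  bad <- is.na(ss$Z)
  ss <- ss[!bad, , drop = FALSE]
  counts["missingZ"] <- sum(bad)

  idx <- match(ss$SNP, ref$SNP)
  counts["notInReference"] <- sum(is.na(idx))
  ss <- ss[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!nrow(ss)) stop("no variants overlap the reference")

  valid <- ss$A1 %in% c("A", "C", "G", "T") & ss$A2 %in% c("A", "C", "G", "T")
  amb <- valid & isAmbiguous(ss$A1, ss$A2)
  counts["ambiguous"] <- sum(amb)
  counts["invalidAlleles"] <- sum(!valid)
  keep <- valid & !amb
  ss <- ss[keep, , drop = FALSE]; idx <- idx[keep]

  rA1 <- ref$A1[idx]; rA2 <- ref$A2[idx]
  same <- ss$A1 == rA1 & ss$A2 == rA2
  swap <- ss$A1 == rA2 & ss$A2 == rA1
  counts["alleleMismatch"] <- sum(!(same | swap))
  ss <- ss[same | swap, , drop = FALSE]
  flip <- swap[same | swap]
  ss$Z[flip] <- -ss$Z[flip]
  # after flipping, record alleles in reference orientation
  ss$A1 <- rA1[same | swap]
  ss$A2 <- rA2[same | swap]
  if ("FRQ" %in% names(ss)) ss$FRQ[flip] <- 1 - ss$FRQ[flip]

  if ("FRQ" %in% names(ss)) {
    maf <- pmin(ss$FRQ, 1 - ss$FRQ)
    failMaf <- !is.na(maf) & maf < minMaf
  } else failMaf <- rep(FALSE, nrow(ss))
  counts["maf"] <- sum(failMaf)
  if ("INFO" %in% names(ss)) {
    failInfo <- !is.na(ss$INFO) & ss$INFO < minInfo
  } else failInfo <- rep(FALSE, nrow(ss))
  counts["info"] <- sum(failInfo)
  ss <- ss[!failMaf & !failInfo, , drop = FALSE]
  counts["retained"] <- nrow(ss)

  out <- ss[, intersect(c("SNP", "A1", "A2", "Z", "N", "FRQ"), names(ss)),
            drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

# Weighted least squares of y on cbind(1, x) with a contiguous block
# jackknife. Returns the full-sample estimate, per-block leave-one-out
# estimates, and jackknife SEs.
.wlsJackknife <- function(x, y, w, nBlocks) {
  n <- length(y)
  X <- cbind(1, x)
  sw <- w
  XtWX <- crossprod(X, X * sw)
  XtWy <- crossprod(X, y * sw)
  est <- unname(drop(solve(XtWX, XtWy)))
  blockId <- ceiling(seq_len(n) / (n / nBlocks))
  blockId[blockId > nBlocks] <- nBlocks
  theta <- matrix(NA_real_, nBlocks, 2L)
  for (b in seq_len(nBlocks)) {
    sel <- blockId == b
    Xb <- X[sel, , drop = FALSE]
    XtWXb <- XtWX - crossprod(Xb, Xb * sw[sel])
    XtWyb <- XtWy - crossprod(Xb, y[sel] * sw[sel])
    theta[b, ] <- unname(drop(solve(XtWXb, XtWyb)))
  }
  mb <- colMeans(theta)
  se <- sqrt((nBlocks - 1) / nBlocks *
               colSums(sweep(theta, 2L, mb)^2))
  list(est = est, blocks = theta, se = se)
}

# Single LD-score regression of z1*z2 on sqrt(N1*N2)*l2/M with the standard
# two-pass weights; used for both the univariate (z1 == z2) and cross-trait
# cases so that a trait regressed with itself gives identical diagonal and
# off-diagonal estimates.
.ldscRegression <- function(z1, z2, n1, n2, l2, M, nBlocks) {
  y <- z1 * z2
  nn <- sqrt(n1 * n2)
  x <- nn * l2 / M
  l2c <- pmax(l2, 1)
  agg <- function(slopeGuess = NULL) {
    s <- M * (mean(y) - as.numeric(all(z1 == z2))) / mean(nn * l2)
    max(min(s, 1), -1)
  }
  sAgg <- agg()
  h1 <- h2 <- abs(sAgg)
  intercept0 <- if (all(z1 == z2)) 1 else 0
  weightFun <- function(s12, icpt) {
    a1 <- 1 + n1 * h1 * l2 / M
    a2 <- 1 + n2 * h2 * l2 / M
    v <- a1 * a2 + (nn * s12 * l2 / M + icpt)^2
    1 / (l2c * 2 * pmax(v, 1e-8))
  }
  w <- weightFun(sAgg, intercept0)
  fit1 <- .wlsJackknife(x, y, w, nBlocks)
  s1 <- max(min(fit1$est[2], 1), -1)
  w <- weightFun(s1, fit1$est[1])
  .wlsJackknife(x, y, w, nBlocks)
}

.resolveBlocks <- function(nSnps, nBlocks) {
  if (nSnps < 2L * nBlocks) {
    nb <- max(2L, floor(nSnps / 2))
    message("reducing jackknife blocks from ", nBlocks, " to ", nb)
    nb
  } else as.integer(nBlocks)
}

# Merge munged stats with LD scores, ordered by genomic position.
.mergeWithLd <- function(munged, ldscores) {
  m <- merge(as.data.frame(munged), ldscores, by = "SNP")
  if (!nrow(m)) stop("no variants shared between summary stats and LD scores")
  m[order(m$CHR, m$BP), , drop = FALSE]
}

#' Univariate LD-score regression heritability
#'
#' Regresses per-variant chi-square statistics on `N * l2 / M` with a free
#' intercept, standard heteroskedasticity/over-counting weights (recomputed
#' once after an initial pass), and a contiguous block jackknife for the
#' standard errors.
#'
#' @param munged Munged summary statistics (from [mungeSumstats()]): columns
#'   `SNP, Z, N`.
#' @param ldscores LD-score table (from [computeLDScores()]).
#' @param M Number of SNPs the heritability is spread over (default: the
#'   number of regression variants).
#' @param nBlocks Jackknife blocks (default 200; reduced automatically with
#'   a message when there are too few variants).
#' @return A list: `h2`, `h2SE`, `intercept`, `interceptSE`, `M`, `nSnps`,
#'   `nBlocks`.
#' @export
ldscH2 <- function(munged, ldscores, M = NULL, nBlocks = 200L) {
  d <- .mergeWithLd(munged, ldscores)
  if (is.null(M)) M <- nrow(d)
  if (M <= 0) stop("M must be positive")
  nBlocks <- .resolveBlocks(nrow(d), nBlocks)
  fit <- .ldscRegression(d$Z, d$Z, d$N, d$N, d$L2, M, nBlocks)
  list(h2 = fit$est[2], h2SE = fit$se[2],
       intercept = fit$est[1], interceptSE = fit$se[1],
       M = M, nSnps = nrow(d), nBlocks = nBlocks)
}

#' Bivariate LD-score regression: genetic covariance and correlation
#'
#' Estimates the 2x2 genetic covariance matrix `S` of two traits by LD-score
#' regression on the variants shared by both munged inputs and the LD-score
#' table (diagonal from chi-square regressions, off-diagonal from the
#' `Z1*Z2` cross-trait regression with a free cross-trait intercept), and its
#' 3x3 sampling covariance `V` by a joint contiguous block jackknife. The
#' genetic correlation is `rg = S12 / sqrt(S11 * S22)` with a jackknife SE.
#'
#' @param munged1,munged2 Munged summary statistics of the two traits, both
#'   aligned to the same reference.
#' @param ldscores LD-score table.
#' @param M SNP count for the polygenicity scale (default: shared variants).
#' @param nBlocks Jackknife blocks (default 200).
#' @param traits Length-2 labels.
#' @return A [GeneticCovariance-class] object.
#' @export
ldscRG <- function(munged1, munged2, ldscores, M = NULL, nBlocks = 200L,
                   traits = c("trait1", "trait2")) {
  m1 <- as.data.frame(munged1)
  m2 <- as.data.frame(munged2)
  idx <- match(m1$SNP, m2$SNP)
  ok <- !is.na(idx)
  if (!any(ok)) stop("no variants shared between the two munged inputs")
  m1 <- m1[ok, , drop = FALSE]
  m2 <- m2[idx[ok], , drop = FALSE]
  same <- m1$A1 == m2$A1 & m1$A2 == m2$A2
  swap <- m1$A1 == m2$A2 & m1$A2 == m2$A1
  m2$Z[swap] <- -m2$Z[swap]
  keep <- same | swap
  m1 <- m1[keep, , drop = FALSE]; m2 <- m2[keep, , drop = FALSE]

  d <- .mergeWithLd(m1, ldscores)
  m2 <- m2[match(d$SNP, m1$SNP), , drop = FALSE]
  if (is.null(M)) M <- nrow(d)
  nBlocks <- .resolveBlocks(nrow(d), nBlocks)

  f11 <- .ldscRegression(d$Z, d$Z, d$N, d$N, d$L2, M, nBlocks)
  f22 <- .ldscRegression(m2$Z, m2$Z, m2$N, m2$N, d$L2, M, nBlocks)
  f12 <- .ldscRegression(d$Z, m2$Z, d$N, m2$N, d$L2, M, nBlocks)

  S <- matrix(c(f11$est[2], f12$est[2], f12$est[2], f22$est[2]), 2L, 2L,
              dimnames = list(traits, traits))
  blocks <- cbind(f11$blocks[, 2L], f12$blocks[, 2L], f22$blocks[, 2L])
  mb <- colMeans(blocks)
  dev <- sweep(blocks, 2L, mb)
  V <- (nBlocks - 1) / nBlocks * crossprod(dev)
  dimnames(V) <- list(c("S11", "S12", "S22"), c("S11", "S12", "S22"))

  rg <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  denomB <- blocks[, 1L] * blocks[, 3L]
  rgBlocks <- ifelse(denomB > 0, blocks[, 2L] / sqrt(pmax(denomB, 1e-12)),
                     NA_real_)
  okB <- !is.na(rgBlocks)
  nb <- sum(okB)
  rgSE <- if (nb >= 2L)
    sqrt((nb - 1) / nb * sum((rgBlocks[okB] - mean(rgBlocks[okB]))^2))
  else NA_real_
  rgP <- zToP(rg / rgSE)

  methods::new("GeneticCovariance",
    S = S, V = V,
    intercepts = c(stats::setNames(c(f11$est[1], f22$est[1]), traits),
                   cross = f12$est[1]),
    M = as.numeric(M), nBlocks = nBlocks, traits = traits,
    rg = rg, rgSE = rgSE, rgP = rgP,
    h2SE = c(sqrt(V[1, 1]), sqrt(V[3, 3])))
}
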