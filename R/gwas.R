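#' Variant quality-control thresholds
#'
#' Defaults reproduce the screening applied to the imputed genotype data:
#' per-variant missingness at most 0.02, minor allele frequency at least
#' 0.001, imputation INFO at least 0.09 and a Hardy-Weinberg exact p-value of
#' at least 1e-4, plus removal of duplicated variants.
#'
#' @param geno Maximum per-variant missingness.
#' @param maf Minimum minor-allele frequency.
#' @param info Minimum imputation INFO score.
#' @param hwe Minimum Hardy-Weinberg exact p-value.
#' @return A named list of thresholds.
#' @export
qcThresholds <- function(geno = 0.02, maf = 0.001, info = 0.09, hwe = 1e-4) {
  thr <- list(geno = geno, maf = maf, info = info, hwe = hwe)
  if (any(unlist(thr) < 0) || any(unlist(thr) > 1))
    stop("all QC thresholds must lie in [0, 1]")
  thr
}

#' Variant quality control
#'
#' Removes variants with missingness above `geno`, minor allele frequency
#' below `maf`, INFO below `info`, Hardy-Weinberg exact p below `hwe`, and
#' duplicates (same id, or same chrom:pos:ref:alt), keeping the first
#' occurrence. Hardy-Weinberg is tested on genotype counts from rounded
#' dosages.
#'
#' @param genotypes A [GenotypeData-class].
#' @param thresholds A list from [qcThresholds()].
#' @return A list: `genotypes` (filtered [GenotypeData-class]) and `report`
#'   (named counts of variants failing each filter -- a variant can fail
#'   several -- plus `removed` and `retained`).
#' @export
variantQC <- function(genotypes, thresholds = qcThresholds()) {
  D <- dosages(genotypes)
  vi <- variantInfo(genotypes)
  m <- nrow(D)

  missRate <- rowMeans(is.na(D))
  failGeno <- missRate > thresholds$geno

  af <- rowMeans(D, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  failMaf <- maf < thresholds$maf

  failInfo <- vi$INFO < thresholds$info

  G <- round(D)
  hweP <- vapply(seq_len(m), function(j) {
    g <- G[j, ]
    g <- g[!is.na(g)]
    hweExactTest(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  failHwe <- hweP < thresholds$hwe

  key <- paste(vi$CHR, vi$BP, vi$REF, vi$ALT, sep = ":")
  failDup <- duplicated(key) | duplicated(vi$SNP)

  fail <- failGeno | failMaf | failInfo | failHwe | failDup
  if (all(fail))
    stop("variant QC removed every variant")
  report <- c(geno = sum(failGeno), maf = sum(failMaf),
              info = sum(failInfo), hwe = sum(failHwe),
              dup = sum(failDup),
              removed = sum(fail), retained = sum(!fail))
  list(genotypes = genotypes[!fail, ], report = report)
}

#' Build a covariate matrix from a cohort table
#'
#' Converts the named cohort columns into a numeric design matrix (no
#' intercept). `CENTRE` is treated as a factor (assessment centre) and
#' expanded into indicator columns.
#'
#' @param cohort A cohort data.frame.
#' @param covars Column names to use; defaults to the standard association
#'   covariates: sex, age, assessment centre, genotyping array and the first
#'   eight principal components.
#' @return A numeric matrix with one row per cohort row.
#' @export
covariateMatrix <- function(cohort,
                            covars = c("SEX", "AGE", "CENTRE", "ARRAY",
                                       paste0("PC", 1:8))) {
  covars <- intersect(covars, names(cohort))
  if (!length(covars)) return(NULL)
  df <- cohort[, covars, drop = FALSE]
  if ("CENTRE" %in% names(df)) df$CENTRE <- factor(df$CENTRE)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1L, drop = FALSE]  # drop intercept
}

# Lightweight logistic IRLS (Newton scoring via weighted least squares on
# the square-root-weighted design). Returns coefficients, SEs from the
# observed information, and convergence/boundary flags. A warm `start`
# (e.g. the covariate-only fit) saves iterations in per-variant scans.
logisticFit <- function(X, y, start = NULL, maxit = 30L, tol = 1e-9) {
  p <- ncol(X)
  failed <- function(flag)
    list(coef = rep(NA_real_, p), se = rep(NA_real_, p),
         converged = FALSE, flag = flag)
  p0 <- mean(y)
  beta <- if (is.null(start)) c(log(p0 / (1 - p0)), numeric(p - 1L))
          else start
  converged <- FALSE
  fit <- NULL
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    sw <- sqrt(w)
    z <- eta + (y - mu) / w
    fit <- .lm.fit(X * sw, z * sw)
    if (fit$rank < p) return(failed("collinear"))
    nb <- numeric(p)
    nb[fit$pivot] <- fit$coefficients
    if (max(abs(nb - beta)) / max(1, max(abs(nb))) < tol) {
      beta <- nb
      converged <- TRUE
      break
    }
    beta <- nb
  }
  eta <- drop(X %*% beta)
  boundary <- max(abs(eta)) > 25   # fitted probabilities pinned at 0/1
  # information matrix inverse from the final weighted QR
  R <- fit$qr[seq_len(p), , drop = FALSE]
  cv <- tryCatch(chol2inv(R), error = function(e) NULL)
  if (is.null(cv)) return(failed("collinear"))
  se <- numeric(p)
  se[fit$pivot] <- sqrt(diag(cv))
  ok <- converged && !boundary
  list(coef = beta, se = se, converged = ok,
       flag = if (ok) "ok" else "nonconverged")
}

#' Per-variant association GWAS
#'
#' For a binary phenotype, fits per variant a logistic regression of case
#' status on allele dosage plus covariates; `BETA` is the dosage coefficient
#' (log-odds per effect allele), the SE comes from the observed information,
#' and the two-sided p-value from the Wald Z. For a quantitative phenotype
#' (`model = "linear"`) ordinary least squares is used with the identical
#' output schema. An optional `conditionSnp` adds that variant's dosage as a
#' covariate (conditional analysis); when the condition variant is perfectly
#' collinear with the tested variant, the record is flagged rather than
#' silently dropped. Per-variant fits use complete cases; degenerate fits
#' (perfect separation, non-convergence, collinearity) yield records with
#' missing `BETA`/`SE` and a `FLAG`.
#'
#' @param genotypes A [GenotypeData-class].
#' @param phenotype Numeric vector, one value per sample: 0/1 case status
#'   (logistic) or a quantitative trait (linear). `NA` allowed.
#' @param covariates Optional numeric covariate matrix/data.frame (see
#'   [covariateMatrix()]).
#' @param model `"logistic"` or `"linear"`.
#' @param conditionSnp Optional variant id to condition on.
#' @return A [SumStats-class] with effect allele `A1 = ALT` and a `FLAG`
#'   column (`"ok"`, `"nonconverged"`, `"collinear"`).
#' @export
runGWAS <- function(genotypes, phenotype, covariates = NULL,
                    model = c("logistic", "linear"), conditionSnp = NULL) {
  model <- match.arg(model)
  D <- dosages(genotypes)
  vi <- variantInfo(genotypes)
  m <- nrow(D); n <- ncol(D)
  stopifnot(length(phenotype) == n)
  y <- as.numeric(phenotype)
  if (model == "logistic") {
    lv <- unique(y[!is.na(y)])
    if (!all(lv %in% c(0, 1)) || length(lv) < 2L)
      stop("logistic model requires a 0/1 phenotype with both classes")
  }
  C <- NULL
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    stopifnot(nrow(C) == n)
  }
  condIdx <- NULL
  if (!is.null(conditionSnp)) {
    condIdx <- match(conditionSnp, vi$SNP)
    if (is.na(condIdx)) stop("conditionSnp not found in genotypes")
    C <- cbind(C, COND = D[condIdx, ])
  }

  keep <- !is.na(y)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  anyDosNA <- anyNA(D)

  beta <- se <- rep(NA_real_, m)
  nUsed <- integer(m)
  flag <- rep("ok", m)

  condCollinear <- function(g, gc) {
    v <- stats::var(g)
    if (v == 0) return(TRUE)
    r <- suppressWarnings(cor(g, gc))
    !is.na(r) && r^2 > 1 - 1e-10
  }

  if (model == "linear" && !anyDosNA) {
    # vectorised OLS via residualisation against the covariate space
    yk <- y[keep]
    Dk <- D[, keep, drop = FALSE]
    X0 <- cbind(`(Intercept)` = rep(1, sum(keep)),
                if (!is.null(C)) C[keep, , drop = FALSE])
    qrX <- qr(X0)
    k <- qrX$rank
    Q <- qr.Q(qrX)[, seq_len(k), drop = FALSE]
    yr <- yk - Q %*% crossprod(Q, yk)
    num <- drop(Dk %*% yr)
    DQ <- Dk %*% Q
    den <- rowSums(Dk^2) - rowSums(DQ^2)
    sst <- sum(yr^2)
    df <- sum(keep) - k - 1L
    ok <- den > 1e-8 * sum(keep)
    # guard against conditioning on a collinear variant
    if (!is.null(condIdx)) {
      gc <- D[condIdx, keep]
      ok <- ok & vapply(seq_len(m), function(j)
        !condCollinear(Dk[j, ], gc), logical(1))
    }
    b <- ifelse(ok, num / den, NA_real_)
    rss <- pmax(sst - ifelse(ok, num^2 / den, 0), 0)
    s2 <- rss / df
    beta <- b
    se <- ifelse(ok, sqrt(s2 / den), NA_real_)
    flag <- ifelse(ok, "ok", "collinear")
    nUsed <- rep(sum(keep), m)
  } else {
    X0 <- cbind(`(Intercept)` = rep(1, n),
                if (!is.null(C)) C,
                DOSE = 0)
    dcol <- ncol(X0)
    warmStart <- NULL
    if (model == "logistic" && !anyDosNA) {
      base <- logisticFit(X0[keep, -dcol, drop = FALSE], y[keep])
      if (base$flag == "ok") warmStart <- c(base$coef, 0)
    }
    for (j in seq_len(m)) {
      g <- D[j, ]
      use <- keep & !is.na(g)
      nUsed[j] <- sum(use)
      if (nUsed[j] < dcol + 1L) { flag[j] <- "nonconverged"; next }
      if (!is.null(condIdx) && condCollinear(g[use], D[condIdx, use])) {
        flag[j] <- "collinear"; next
      }
      X0[, dcol] <- g
      X <- X0[use, , drop = FALSE]
      if (model == "logistic") {
        yj <- y[use]
        if (length(unique(yj)) < 2L) { flag[j] <- "nonconverged"; next }
        fit <- logisticFit(X, yj, start = warmStart)
        flag[j] <- fit$flag
        if (fit$flag == "ok") {
          beta[j] <- fit$coef[dcol]
          se[j] <- fit$se[dcol]
        }
      } else {
        fit <- stats::lm.fit(X, y[use])
        if (fit$rank < dcol || is.na(fit$coefficients[dcol])) {
          flag[j] <- "collinear"; next
        }
        rss <- sum(fit$residuals^2)
        df <- nUsed[j] - fit$rank
        R <- qr.R(fit$qr)
        cv <- chol2inv(R)
        # undo pivoting
        piv <- fit$qr$pivot
        cvFull <- matrix(NA_real_, dcol, dcol)
        cvFull[piv, piv] <- cv
        beta[j] <- fit$coefficients[dcol]
        se[j] <- sqrt(cvFull[dcol, dcol] * rss / df)
      }
    }
  }

  af <- rowMeans(D[, keep, drop = FALSE], na.rm = TRUE) / 2
  z <- beta / se
  SumStats(data.frame(
    SNP = vi$SNP, CHR = vi$CHR, BP = vi$BP,
    A1 = vi$ALT, A2 = vi$REF, FRQ = af,
    BETA = beta, SE = se, Z = z, P = zToP(z),
    N = nUsed, INFO = vi$INFO, FLAG = flag,
    stringsAsFactors = FALSE))
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (length(m) != 1L || is.na(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Replication sign test for lead SNPs
#'
#' Harmonises the lead SNPs' alleles between discovery and replication
#' (flipping the replication effect when A1/A2 are reversed), counts
#' direction-concordant effects, and returns the exact one-sided binomial
#' p-value `P(X >= k | n, 1/2)` together with per-SNP replication p-values
#' and Bonferroni flags at `0.05 / n`.
#'
#' @param discoveryLeads A [SumStats-class] (or data.frame) of discovery lead
#'   SNPs with `SNP, A1, A2, BETA`.
#' @param replication A [SumStats-class] (or data.frame) of replication
#'   results.
#' @return A list: `nConcordant`, `nTested`, `p` (exact binomial),
#'   `bonferroni` (per-SNP replication threshold), and `perSnp` data.frame.
#' @export
signTestReplication <- function(discoveryLeads, replication) {
  d <- as.data.frame(discoveryLeads)
  r <- as.data.frame(replication)
  idx <- match(d$SNP, r$SNP)
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " lead SNPs absent from replication; excluded")
    d <- d[!missing, , drop = FALSE]
    idx <- idx[!missing]
  }
  if (!nrow(d)) stop("no lead SNPs overlap the replication results")
  r <- r[idx, , drop = FALSE]
  same <- d$A1 == r$A1 & d$A2 == r$A2
  flipped <- d$A1 == r$A2 & d$A2 == r$A1
  bad <- !(same | flipped)
  if (any(bad)) {
    warning(sum(bad), " lead SNPs with incompatible alleles; excluded")
    d <- d[!bad, , drop = FALSE]; r <- r[!bad, , drop = FALSE]
    same <- same[!bad]; flipped <- flipped[!bad]
  }
  bRep <- ifelse(flipped, -r$BETA, r$BETA)
  n <- nrow(d)
  conc <- sign(d$BETA) == sign(bRep) & d$BETA != 0 & bRep != 0
  k <- sum(conc)
  p <- pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  thr <- bonferroniThreshold(0.05, n)
  list(nConcordant = k, nTested = n, p = p, bonferroni = thr,
       perSnp = data.frame(SNP = d$SNP,
                           BETA_DISC = d$BETA, BETA_REP = bRep,
                           CONCORDANT = conc, P_REP = r$P,
                           SIG_BONFERRONI = !is.na(r$P) & r$P < thr,
                           stringsAsFactors = FALSE))
}
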