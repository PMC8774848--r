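# Squared Pearson correlation between dosage vectors of two variants in the
# reference panel.
.pairR2 <- function(D, i, j) {
  r <- suppressWarnings(cor(D[i, ], D[j, ], use = "complete.obs"))
  if (is.na(r)) 0 else r^2
}

#' Greedy clumping into independent significant SNPs
#'
#' Sorts genome-wide significant variants (`P < pThreshold`) by ascending
#' p-value (ties broken by chromosome, position, then id) and accepts a
#' variant iff its LD `r^2` with every previously accepted variant on the
#' same chromosome is below `r2`. Significant variants absent from the LD
#' reference are retained as independent, with a warning.
#'
#' @param sumstats A [SumStats-class] or data.frame with `SNP, CHR, BP, P`.
#' @param reference A [GenotypeData-class] LD reference panel.
#' @param pThreshold Genome-wide significance threshold (default 5e-8).
#' @param r2 Clumping threshold (default 0.6); variants at `r^2 >=` this with
#'   an accepted variant are clumped away.
#' @return A data.frame of the independent significant SNPs (rows of
#'   `sumstats`), with attribute `nMissingFromReference`.
#' @export
findIndependentSignificant <- function(sumstats, reference,
                                       pThreshold = 5e-8, r2 = 0.6) {
  ss <- as.data.frame(sumstats)
  sig <- ss[!is.na(ss$P) & ss$P < pThreshold, , drop = FALSE]
  if (!nrow(sig)) {
    out <- sig
    attr(out, "nMissingFromReference") <- 0L
    return(out)
  }
  sig <- sig[order(sig$P, sig$CHR, sig$BP, sig$SNP), , drop = FALSE]
  D <- dosages(reference)
  refIds <- snpIds(reference)
  idx <- match(sig$SNP, refIds)
  nMissing <- sum(is.na(idx))
  if (nMissing > 0L)
    warning(nMissing, " significant variants absent from the LD reference; ",
            "treated as independent")
  accepted <- integer(0)
  for (i in seq_len(nrow(sig))) {
    if (is.na(idx[i])) { accepted <- c(accepted, i); next }
    indep <- TRUE
    for (a in accepted) {
      if (is.na(idx[a]) || sig$CHR[a] != sig$CHR[i]) next
      if (.pairR2(D, idx[i], idx[a]) >= r2) { indep <- FALSE; break }
    }
    if (indep) accepted <- c(accepted, i)
  }
  out <- sig[accepted, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nMissingFromReference") <- nMissing
  out
}

#' Lead SNPs and merged genomic loci
#'
#' Second-stage clumping of the independent significant SNPs at
#' `r^2 < r2Lead` yields the lead SNPs. Candidate SNPs are all reference
#' variants in LD (`r^2 >= r2Candidate`) with any independent significant
#' SNP; each independent significant SNP's LD block spans its candidates, and
#' blocks separated by at most `mergeKb` kb are merged into a single locus.
#' The per-locus index SNP is the member with the smallest p-value.
#'
#' @param sumstats The association results ([SumStats-class] or data.frame).
#' @param reference A [GenotypeData-class] LD reference panel.
#' @param independent Output of [findIndependentSignificant()] (computed if
#'   missing).
#' @param r2Lead Second-stage clumping threshold (default 0.1).
#' @param r2Candidate LD threshold defining candidate SNPs (default 0.6).
#' @param mergeKb Maximum gap, in kb, between LD blocks of one locus
#'   (default 250).
#' @param pThreshold Significance threshold used when `independent` must be
#'   computed (default 5e-8).
#' @return A [LocusTable-class] object.
#' @export
defineLoci <- function(sumstats, reference, independent = NULL,
                       r2Lead = 0.1, r2Candidate = 0.6, mergeKb = 250,
                       pThreshold = 5e-8) {
  ss <- as.data.frame(sumstats)
  if (is.null(independent))
    independent <- findIndependentSignificant(ss, reference,
                                              pThreshold = pThreshold,
                                              r2 = r2Candidate)
  nMissing <- attr(independent, "nMissingFromReference")
  if (is.null(nMissing)) nMissing <- 0L
  if (!nrow(independent))
    stop("no independent significant SNPs; nothing to define loci from")
  ind <- independent[order(independent$P, independent$CHR, independent$BP,
                           independent$SNP), , drop = FALSE]
  D <- dosages(reference)
  refIds <- snpIds(reference)
  refInfo <- variantInfo(reference)
  idx <- match(ind$SNP, refIds)

  # second-stage clumping -> lead SNPs
  leadRows <- integer(0)
  for (i in seq_len(nrow(ind))) {
    if (is.na(idx[i])) { leadRows <- c(leadRows, i); next }
    indep <- TRUE
    for (a in leadRows) {
      if (is.na(idx[a]) || ind$CHR[a] != ind$CHR[i]) next
      if (.pairR2(D, idx[i], idx[a]) >= r2Lead) { indep <- FALSE; break }
    }
    if (indep) leadRows <- c(leadRows, i)
  }
  leads <- ind$SNP[leadRows]

  # candidate SNPs: reference variants in LD with any independent SNP
  candList <- vector("list", nrow(ind))
  for (i in seq_len(nrow(ind))) {
    if (is.na(idx[i])) { candList[[i]] <- character(0); next }
    onChr <- which(refInfo$CHR == ind$CHR[i])
    r2v <- vapply(onChr, function(j) .pairR2(D, idx[i], j), numeric(1))
    candList[[i]] <- refInfo$SNP[onChr[r2v >= r2Candidate]]
  }

  # per-independent-SNP LD block, then merge blocks within mergeKb
  starts <- ends <- integer(nrow(ind))
  for (i in seq_len(nrow(ind))) {
    pos <- c(ind$BP[i], refInfo$BP[match(candList[[i]], refInfo$SNP)])
    starts[i] <- min(pos); ends[i] <- max(pos)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(ind$CHR),
    ranges = IRanges::IRanges(start = starts, end = ends),
    SNP = ind$SNP)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = mergeKb * 1000 + 1)
  # each original block is contained in exactly one merged locus
  locusOf <- GenomicRanges::findOverlaps(gr, merged, select = "first")

  nLoci <- length(merged)
  tab <- data.frame(LOCUS = seq_len(nLoci),
                    CHR = as.character(GenomicRanges::seqnames(merged)),
                    START = GenomicRanges::start(merged),
                    END = GenomicRanges::end(merged),
                    INDEX_SNP = NA_character_, INDEX_P = NA_real_,
                    N_LEAD = 0L, N_IND_SIG = 0L, N_CANDIDATE = 0L,
                    stringsAsFactors = FALSE)
  candPerLocus <- vector("list", nLoci)
  for (l in seq_len(nLoci)) {
    memb <- which(locusOf == l)
    tab$N_IND_SIG[l] <- length(memb)
    tab$N_LEAD[l] <- sum(leadRows %in% memb)
    best <- memb[which.min(ind$P[memb])]
    tab$INDEX_SNP[l] <- ind$SNP[best]
    tab$INDEX_P[l] <- ind$P[best]
    cands <- unique(c(ind$SNP[memb], unlist(candList[memb])))
    candPerLocus[[l]] <- cands
    tab$N_CANDIDATE[l] <- length(cands)
  }
  mc <- S4Vectors::DataFrame(LOCUS = seq_len(nLoci),
                             INDEX_SNP = tab$INDEX_SNP)
  S4Vectors::mcols(merged) <- mc
  methods::new("LocusTable", table = tab, loci = merged,
               independentSnps = ind$SNP, leadSnps = leads,
               candidateSnps = candPerLocus,
               nMissingFromReference = as.integer(nMissing))
}
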