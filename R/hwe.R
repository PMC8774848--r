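#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact test for a biallelic variant: the p-value is the total probability,
#' under the null distribution of heterozygote counts conditional on the
#' allele counts, of all outcomes no more probable than the observed one
#' (the standard SNP exact test). Computed by recurrence on the heterozygote
#' count, so it is stable for large samples.
#'
#' @param nAA,nAB,nBB Genotype counts (homozygous A, heterozygous,
#'   homozygous B).
#' @return The exact p-value.
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
  stopifnot(nAA >= 0, nAB >= 0, nBB >= 0)
  n <- nAA + nAB + nBB
  if (n == 0L) return(1)
  nA <- 2L * nAA + nAB
  nB <- 2L * nBB + nAB
  rare <- min(nA, nB)
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  # start at the null-expected heterozygote count (the distribution's mode,
  # so the recurrence only ever shrinks and cannot overflow)
  midH <- hets[which.min(abs(hets - nA * nB / (2 * n)))]
  iMid <- match(midH, hets)
  probs[iMid] <- 1
  toHoms <- function(h) {
    # given het count h, homozygote counts of the rare and common allele
    homRare <- (rare - h) / 2
    c(homRare, n - h - homRare)
  }
  if (iMid > 1L) for (i in seq(iMid - 1L, 1L)) {
    h <- hets[i + 1L]
    hom <- toHoms(h)
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * (hom[1] + 1) * (hom[2] + 1))
  }
  if (iMid < length(hets)) for (i in seq(iMid + 1L, length(hets))) {
    h <- hets[i - 1L]
    hom <- toHoms(h)
    probs[i] <- probs[i - 1L] * 4 * hom[1] * hom[2] / ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  pObs <- probs[match(nAB, hets)]
  if (is.na(pObs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}
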