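# Internal helpers shared across modules.

# Deterministic per-stage child seed derived from a master seed; keeps values
# inside the 32-bit integer range.
childSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(genotypes = 101L, factors = 211L, phenotypes = 307L,
               split = 401L, misc = 503L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage))
  as.integer((abs(seed) * 7919 + off) %% 2147483587)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Column-standardize a samples x variants matrix to mean 0, variance 1
# (denominator n - 1). Monomorphic columns become 0 with a warning upstream.
standardizeColumns <- function(X) {
  mu <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2L, mu, "-")
  s <- sqrt(colSums(X^2, na.rm = TRUE) / (nrow(X) - 1L))
  s[s == 0] <- 1
  sweep(X, 2L, s, "/")
}

# Two-sided normal p-value from a Z score.
zToP <- function(z) 2 * pnorm(-abs(z))

# Strand-ambiguous allele pair (A/T or C/G)?
isAmbiguous <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}
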