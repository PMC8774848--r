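---
title: "Latent-trait GWAS of cognitive resilience by subtraction: model, assumptions, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-trait GWAS of cognitive resilience by subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cognitive resilience — preserving processing speed into later adulthood —
cannot be measured directly in most biobanks because the same cognitive test
is rarely administered decades apart. The design implemented here uses two
proxy measurements taken in a middle-aged cohort (ages 40–69):

* **Education years (EY)** as a proxy for cognitive performance in early
  adulthood. Because the source data record the age at leaving full-time
  education only for people who did not attend college, college attendees are
  assigned a default of 20 years, and the measure is binarised at
  *years ≤ 17* (below average) versus *above*.
* **Reaction time (RT)** — milliseconds to identify matching pairs — as the
  current measure of processing speed. RT rises with age, so it is first
  corrected using the ordinary least-squares slope of RT on age (centred at
  the sample mean age), log-transformed for normality, and binarised at the
  sample mean of the log corrected values. Ties go to "faster", since the
  split is *less than or equal to* the mean.

Crossing the two binaries yields four quadrant groups and two case–control
contrasts:

| Group | EY | RT | Role |
|---|---|---|---|
| `EYRES_CASE` | below | faster | resilient cases |
| `EYRES_CONTROL` | above | slower | declining controls |
| `NONRES_CASE` | below | slower | consistently low |
| `NONRES_CONTROL` | above | faster | consistently high |

The **EY+Res** GWAS (resilient cases vs declining controls) captures genetic
variance of both education and resilience; the **EY/NonRes** GWAS
(consistently-low vs consistently-high) captures education-related variance
without resilience. Education is so polygenic that it dominates both
contrasts, masking resilience — which is exactly what the subtraction
removes.

## The Cholesky subtraction model

Let $S$ be the $2\times2$ genetic covariance matrix of the two contrasts
(order: EY+Res, EY/NonRes), estimated by LD-score regression together with
the sampling covariance $V$ of its unique elements. The structural model
regresses both contrasts on a latent **EduYears** factor and the EY+Res
contrast additionally on a latent **Resilience** factor, with the two
factors uncorrelated and the contrasts' residual variances fixed at zero:

$$
S_{22} = \lambda_{E,non}^2,\qquad
S_{12} = \lambda_{E,ey}\,\lambda_{E,non},\qquad
S_{11} = \lambda_{E,ey}^2 + \lambda_{R,ey}^2 .
$$

The model is *just-identified*: the loadings are the Cholesky factor of $S$
in closed form,

$$
\lambda_{E,non}=\sqrt{S_{22}},\quad
\lambda_{E,ey}=S_{12}/\sqrt{S_{22}},\quad
\lambda_{R,ey}=\sqrt{S_{11}-S_{12}^2/S_{22}},
$$

and any weighted-least-squares fit of the same model reaches the same
solution (the test suite checks this against an independent numerical
minimiser to $10^{-6}$). When $S$ is not positive semidefinite the model is
inadmissible and `fitCholesky()` stops rather than clamping — a silent clamp
would fabricate a Resilience factor.

Per variant, the observed standardized effects
$b_k = Z_k/\sqrt{N_k\,2pq}$ (variant variance $2pq$ from a supplied allele
frequency reference) solve the path system

$$
\beta_{Edu} = b_2/\lambda_{E,non},\qquad
\beta_{Res} = (b_1 - \lambda_{E,ey}\beta_{Edu})/\lambda_{R,ey},
$$

again just-identified, so the reconstruction identities
$\lambda_{E,ey}\beta_{Edu}+\lambda_{R,ey}\beta_{Res}=b_1$ and
$\lambda_{E,non}\beta_{Edu}=b_2$ hold exactly. Standard errors follow by
the delta method from $\mathrm{Var}(b_k)=1/(N_k 2pq)$ and the cross-trait
covariance implied by the LDSC cross-trait intercept. Because the two
contrasts use disjoint individuals, the default cross-covariance is zero.
Sampling uncertainty of the genome-wide loadings is *excluded* from the
per-variant SEs by default (loadings estimated from genome-wide data are
treated as fixed); `includeLoadingUncertainty = TRUE` propagates it.

The **effective sample size** of a latent trait inverts the
standardization: $\hat N = (Z/\beta)^2/(2\,\mathrm{MAF}(1-\mathrm{MAF}))$,
averaged over variants with MAF strictly between 0.10 and 0.40 — low- and
high-frequency variants bias the inversion, hence the trim. The mean (not
the median) of the per-variant values is reported; on stats constructed with
$Z=\beta\sqrt{N\,2pq}$ the inversion returns $N$ exactly.

## LD-score regression machinery

* **LD scores.** For variant $j$,
  $\ell_j = 1 + \sum_{k \ne j} \left[r^2_{jk} - (1-r^2_{jk})/(n-2)\right]$
  over variants within a 1,000 kb window (configurable); the adjustment
  makes unlinked pairs contribute zero in expectation, and the self term is
  exactly 1.
* **Munging.** Summary statistics are intersected with a reference,
  strand-ambiguous (A/T, C/G) variants dropped, Z negated on allele swaps,
  and MAF ≥ 0.01 / INFO ≥ 0.9 filters applied (defaults, configurable).
* **Regression.** $Z_1 Z_2$ is regressed on $\sqrt{N_1 N_2}\,\ell/M$ with a
  free intercept. The same routine serves the univariate case
  ($Z_1 = Z_2$, intercept near 1) and the cross-trait case (intercept near 0
  for disjoint samples), so a trait regressed with itself returns
  $r_g = 1$ exactly. Weights are the standard over-counting ×
  heteroskedasticity product, $1/\max(\ell,1)$ times the inverse squared
  expected variance of the product, recomputed once after an initial pass
  seeded by the aggregate (method-of-moments) estimate.
* **Jackknife.** $V$ comes from a contiguous block jackknife over the three
  unique elements of $S$ jointly, so its diagonal equals the squared SEs of
  $S_{11}, S_{12}, S_{22}$ by construction. The default is 200 blocks,
  automatically reduced for small panels. **Blocks must be wider than the
  LD blocks of the panel** — on the synthetic panels below (LD blocks of 25
  variants, $M = 2000$) the validation suite uses 50 jackknife blocks of 40
  variants; with blocks narrower than the LD range the leave-one-out
  estimates are not exchangeable and SEs are underestimated.

The cross-trait intercept is left free: the two contrasts come from
disjoint individuals of one cohort, so the expected intercept is zero, and
freeness is the safe default. No constrained-intercept mode is provided.

## The synthetic cohort: what it emulates and what it does not

`simulationConfig()` defaults define the desk-scale study conditions used
throughout the validation suite:

* 20,000 individuals aged 40–69; 2,000 variants with allele frequencies
  uniform on (0.05, 0.5); fully polygenic architecture (every variant
  causal) unless a sparse causal count is requested.
* Two **independent** latent factors: an education factor with
  $h^2 = 0.3$ and a resilience factor with $h^2 = 0.2$. Causal effects are
  drawn independently, so the true genetic correlation is zero; effects and
  residuals are rescaled so the realised genetic share equals the configured
  $h^2$ exactly.
* Education years are a monotone quantile map of the education factor onto
  14–20 years, with the top 20% flagged as college (years recorded as
  missing, mirroring the source cohort's recording convention) and the
  binarisation boundary placed so the ≤ 17 split is 50/50.
* Reaction time:
  `RT = 530 + 3·(age − mean age) − 30·F_edu − 60·F_res + nuisance + N(0, 80²)`
  ms. Both factors speed responses up, so resilient individuals (high
  resilience factor) are fast despite low education. The age slope
  (3 ms/year), baseline and noise put the age–RT correlation and the RT
  spread in the realistic range for a matching-pairs task. Sex, assessment
  centre, genotyping array and eight principal components are generated as
  nuisance covariates with small effects.
* Genotypes are independent binomial sites by default. For LD-dependent
  tools (LD scores, clumping, conditional analysis, and the end-to-end
  acceptance run), haplotypes are drawn from a latent Gaussian AR(1) within
  blocks of 25 adjacent variants (latent correlation 0.85), thresholded at
  the allele frequency. Two things motivate using LD blocks in the
  end-to-end run even though independent sites are the generator default:
  real genomes have LD, and with *no* variation in LD scores the LD-score
  regression slope is unidentified (the regressor is constant), making
  heritability and genetic covariance estimation meaningless.

Not emulated: imputation error structure (INFO is 1 everywhere),
relatedness, population stratification beyond the nuisance PC columns,
X chromosome, and realistic marker density (2,000 variants spaced 25 kb on
one chromosome). Passing tests therefore validate the *machinery* — the
phenotype construction, association models, LDSC estimators, subtraction
algebra and locus definition — not the biology of any real cohort; the
published real-data results (13 loci, $h^2 = 0.13$, Neff = 111,316) require
the restricted-access cohort itself and are out of desk-scale reach.

Seeding: one master seed in the configuration; each stage (genotypes,
factors, phenotypes, split) uses a deterministically derived child seed, so
identical configurations give byte-identical exported fixtures.

## Association model and quality control

Per-variant association is logistic regression of case status on allele
dosage plus covariates (sex, age, assessment centre, array, PC1–PC8 by
convention), matching the standard treatment of binary phenotypes; the
quantitative mode is ordinary least squares with the same output schema.
Betas are log-odds per effect allele; SEs come from the observed
information; p-values from the Wald Z, matching the Z-based LDSC downstream.
The solver is a compact iteratively reweighted least-squares Newton scheme
(validated against `glm` to $10^{-6}$ including SEs); perfect separation,
non-convergence and collinearity (including conditioning a variant on
itself) yield flagged records with missing effect — never silent drops.
Conditional analysis adds the dosage of a named variant as a covariate,
the standard way of testing whether nearby signals are independent.

Variant QC applies missingness ≤ 0.02, MAF ≥ 0.001, INFO ≥ 0.09 and a
Hardy–Weinberg exact-test p ≥ 1e-4, then removes duplicates
(chrom:pos:ref:alt or id), keeping the first. The HWE exact test conditions
on allele counts and is computed by recurrence; the suite checks it against
a direct log-factorial enumeration.

## Locus definition

Two-stage greedy clumping, following the convention of the standard
post-GWAS annotation platform: significant variants ($p < 5\times10^{-8}$)
are scanned in order of ascending p (ties: position, then id), and a variant
is *independent significant* iff its $r^2$ with every previously accepted
variant is below 0.6. A second pass at $r^2 < 0.1$ yields *lead SNPs*.
*Candidate SNPs* are all reference variants at $r^2 \ge 0.6$ with an
independent significant SNP; each independent SNP's LD block spans its
candidates, and blocks whose hulls are within 250 kb of each other are
merged into one locus (hull-to-hull, gaps of exactly 250 kb merge). $r^2$
is the squared Pearson correlation of unphased dosages in the reference
panel. Significant variants absent from the panel are retained as
independent with a warning, not dropped. The per-locus index SNP is the
smallest-p member; because the greedy pass accepts smaller p first, the
index SNP is always independent significant.

## Replication protocol

The cohort is split 81% / 19% into discovery and replication (deterministic
given a seed; individuals can be forced into replication, mirroring the
reservation of an imaging subsample). Discovery lead SNPs are compared with
the replication GWAS after allele harmonisation; the sign test is the exact
binomial tail $P(X \ge k \mid n, 1/2)$, and per-SNP replication uses the
Bonferroni threshold $0.05/n$. Ten concordant SNPs out of ten give
$p = 2^{-10} = 9.77\times10^{-4}$.

## Numerical choices and edge cases

* Education/RT missing values are excluded before threshold computation,
  with counts reported; all-missing education is an error.
* Zero age variance makes the RT age slope undefined — an error, not NaN.
* `S22 = 0` (EduYears undefined) and non-PSD $S$ stop the Cholesky fit.
* `effectiveN()` errors when the MAF trim empties the panel and excludes
  zero-beta variants with a count.
* LD-score self terms are exactly 1; pairwise adjusted $r^2$ may be
  slightly negative (its null expectation is zero), so individual scores
  can dip slightly below 1 for isolated variants.
* Tie-breaking in clumping is deterministic (p, then chromosome, position,
  id), so row order never affects the locus table.

## Validation design

Every operation is tested against an independent oracle where one exists:
closed-form 2×2 log odds ratio and `glm` for the association engine; exact
linear chi-square constructions (slope recovered to $10^{-8}$) and
parameter-recovery simulations for LDSC; a numerical WLS minimiser for the
Cholesky loadings and the per-SNP subtraction; direct log-factorial
enumeration for the HWE exact test; hand-derived counts on constructed LD
fixtures for the locus tools. The end-to-end acceptance run (5 seeds at the
study conditions above) checks that the post-subtraction genetic correlation
between latent Resilience and latent EduYears lies within 2 jackknife SEs of
zero — the synthetic analogue of the published near-zero correlation — that
latent Resilience effects correlate with the resilience truth better than
with the education truth, and that LDSC heritability and Cholesky loadings
recover known-truth quantitative constructions within 2 pooled SEs across
seeds (pooling across seeds applies the 2-SE criterion to the whole
experiment rather than multiplying one-in-twenty chance failures across 25
separate comparisons).

## Known limitations

* LDSC slope/intercept separation is weak at desk scale ($M = 2000$,
  LD scores spanning only ~1–3.5): SEs are honest but large, and the
  intercept is estimated far from the bulk of the design. Real applications
  use millions of variants and reference LD scores spanning two orders of
  magnitude.
* The generative mapping from latent factors to education years and
  reaction time is a modelling choice; the source design only constrains
  the binarised forms.
* No mixed-model or saddlepoint association, no Firth fallback (degenerate
  fits are flagged instead), no partitioned heritability, no
  sample-overlap correction beyond the free cross-trait intercept, and no
  fine-mapping — locus definition stops at merged genomic loci.
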