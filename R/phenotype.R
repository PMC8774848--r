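#' Binarize education years
#'
#' College attendees receive a default score of 20 years; the binary
#' education phenotype is `"below"` when years are less than or equal to 17
#' and `"above"` otherwise. Individuals missing both the years and the
#' college indicator get `NA` and are reported in the `nMissingEducation`
#' attribute.
#'
#' @param cohort A data.frame with `EDU_YEARS` (years, possibly missing) and
#'   optionally `COLLEGE` (0/1).
#' @return `cohort` with added columns `EDU_YEARS_FILLED` and `EY_BINARY`
#'   (`"below"`/`"above"`), and attribute `nMissingEducation`.
#' @export
binarizeEducation <- function(cohort) {
  if (!"EDU_YEARS" %in% names(cohort))
    stop("cohort must contain EDU_YEARS")
  years <- cohort$EDU_YEARS
  if ("COLLEGE" %in% names(cohort))
    years[!is.na(cohort$COLLEGE) & cohort$COLLEGE == 1L] <- 20
  nMissing <- sum(is.na(years))
  if (nMissing == length(years))
    stop("all individuals are missing education information")
  if (nMissing > 0L)
    message(nMissing, " individuals missing education information; excluded")
  cohort$EDU_YEARS_FILLED <- years
  cohort$EY_BINARY <- ifelse(is.na(years), NA_character_,
                             ifelse(years <= 17, "below", "above"))
  attr(cohort, "nMissingEducation") <- nMissing
  cohort
}

#' Age-correct, log-transform and binarize reaction time
#'
#' Computes the ordinary least-squares slope of reaction time on age
#' (`cov(age, RT) / var(age)`) on the analysis sample, removes the age trend
#' around the sample mean age, takes the natural log, and splits at the
#' sample mean of the log corrected values. Ties at the threshold are
#' assigned to `"faster"` (the split is "less than or equal to the mean").
#' Individuals with missing or non-positive (raw or corrected) reaction time
#' are excluded from both the model and the split, with a warning count.
#'
#' @param cohort A data.frame with `RT_MS` (ms) and `AGE` (years).
#' @return A list: `cohort` (with added `RT_LN_CORR` and `RT_BINARY`
#'   columns) and `model` (list with `slope` in ms/year, `referenceAge`,
#'   `threshold` in natural-log units, and `nExcluded`).
#' @export
correctRT <- function(cohort) {
  stopifnot(all(c("RT_MS", "AGE") %in% names(cohort)))
  ok <- !is.na(cohort$RT_MS) & !is.na(cohort$AGE) & cohort$RT_MS > 0
  nBad <- sum(!ok)
  if (sum(ok) < 2L) stop("fewer than 2 usable reaction-time measurements")
  age <- cohort$AGE[ok]
  rt <- cohort$RT_MS[ok]
  if (var(age) == 0)
    stop("age has zero variance; age-correction slope is undefined")
  slope <- cov(age, rt) / var(age)
  refAge <- mean(age)
  corr <- cohort$RT_MS - slope * (cohort$AGE - refAge)
  bad2 <- ok & corr <= 0
  if (any(bad2)) {
    warning(sum(bad2), " corrected reaction times were non-positive; excluded")
    ok <- ok & !bad2
  }
  nExcluded <- nBad + sum(bad2)
  lnCorr <- rep(NA_real_, nrow(cohort))
  lnCorr[ok] <- log(corr[ok])
  threshold <- mean(lnCorr[ok])
  cohort$RT_LN_CORR <- lnCorr
  cohort$RT_BINARY <- ifelse(is.na(lnCorr), NA_character_,
                             ifelse(lnCorr <= threshold, "faster", "slower"))
  list(cohort = cohort,
       model = list(slope = slope, referenceAge = refAge,
                    threshold = threshold, nExcluded = nExcluded))
}

#' Assign the four quadrant groups
#'
#' Crosses the binary education and reaction-time phenotypes into the four
#' quadrant groups: resilient cases had below-average education years
#' previously and faster-than-average reaction time now
#' (`EYRES_CASE`); their controls are above/slower (`EYRES_CONTROL`). The
#' consistent-performance groups form the second contrast: below/slower
#' (`NONRES_CASE`) versus above/faster (`NONRES_CONTROL`).
#'
#' @param cohort A data.frame with `EY_BINARY` and `RT_BINARY` columns (from
#'   [binarizeEducation()] and [correctRT()]).
#' @return `cohort` with an added `GROUP` column (`NA` where either binary
#'   is missing).
#' @export
assignQuadrants <- function(cohort) {
  stopifnot(all(c("EY_BINARY", "RT_BINARY") %in% names(cohort)))
  ey <- cohort$EY_BINARY
  rt <- cohort$RT_BINARY
  grp <- rep(NA_character_, nrow(cohort))
  grp[ey == "below" & rt == "faster"] <- "EYRES_CASE"
  grp[ey == "above" & rt == "slower"] <- "EYRES_CONTROL"
  grp[ey == "below" & rt == "slower"] <- "NONRES_CASE"
  grp[ey == "above" & rt == "faster"] <- "NONRES_CONTROL"
  cohort$GROUP <- grp
  cohort
}

#' Build all derived phenotypes
#'
#' Runs [binarizeEducation()], [correctRT()] and [assignQuadrants()] in
#' sequence.
#'
#' @param cohort A covariate/phenotype data.frame (see
#'   [simulateCohortPhenotypes()] for the column conventions).
#' @return A list: `cohort` (with `EY_BINARY`, `RT_BINARY`, `GROUP` columns)
#'   and `rtModel` (the reaction-time correction model).
#' @export
buildPhenotypes <- function(cohort) {
  cohort <- binarizeEducation(cohort)
  rt <- correctRT(cohort)
  cohort <- assignQuadrants(rt$cohort)
  list(cohort = cohort, rtModel = rt$model)
}

#' Split a cohort into discovery and replication samples
#'
#' Draws a deterministic (given `seed`) partition with
#' `round(fractionDiscovery * N)` individuals in discovery and the remainder
#' in replication. Individuals named in `forceReplication` (for example,
#' participants reserved for a follow-up imaging subsample) are placed in the
#' replication set before the random draw.
#'
#' @param cohort A data.frame with an `IID` column.
#' @param fractionDiscovery Discovery fraction in (0, 1); default 0.81.
#' @param seed Integer seed for the random assignment.
#' @param forceReplication Optional character vector of IIDs forced into the
#'   replication sample.
#' @return A list with data.frames `discovery` and `replication`, and a
#'   `membership` data.frame (`IID`, `SPLIT`).
#' @export
splitDiscoveryReplication <- function(cohort, fractionDiscovery = 0.81,
                                      seed = 1L, forceReplication = NULL) {
  if (fractionDiscovery <= 0 || fractionDiscovery >= 1)
    stop("fractionDiscovery must be in (0, 1)")
  n <- nrow(cohort)
  nDisc <- round(fractionDiscovery * n)
  forced <- which(cohort$IID %in% forceReplication)
  if (n - length(forced) < nDisc)
    stop("too many forced replication members for the requested fraction")
  pool <- setdiff(seq_len(n), forced)
  discIdx <- withSeed(seed, sort(sample(pool, nDisc)))
  split <- ifelse(seq_len(n) %in% discIdx, "discovery", "replication")
  list(discovery = cohort[split == "discovery", , drop = FALSE],
       replication = cohort[split == "replication", , drop = FALSE],
       membership = data.frame(IID = cohort$IID, SPLIT = split,
                               stringsAsFactors = FALSE))
}
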