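#' Expected event count for a cohort
#'
#' Sums each woman's model probability of breast cancer over her own
#' observed follow-up (default) or over a fixed horizon applied to all
#' women.
#'
#' @param cohort data.frame with columns `entry_age`, `follow_up`
#'   (years, positive) and one code column per scheme factor (a
#'   `rr` column, if present, takes precedence over re-deriving the
#'   composite RR).
#' @param region a [RegionModel-class].
#' @param scheme a [RiskFactorScheme-class].
#' @param horizon optional fixed horizon in years; when supplied, every
#'   woman's risk is projected over `min(horizon, grid end - entry_age)`
#'   instead of her realized follow-up.
#' @return expected number of events (0 for an empty cohort).
#' @export
expectedEvents <- function(cohort, region, scheme = defaultScheme(), horizon = NULL) {
  stopifnot(is(region, "RegionModel"))
  if (nrow(cohort) == 0L) return(0)
  r <- cohortRR(cohort, scheme)
  tau <- if (is.null(horizon)) cohort$follow_up else rep(horizon, nrow(cohort))
  if (any(tau <= 0)) stop("follow-up must be positive for every record")
  rng <- gridRange(region@baseline)
  bad <- which(cohort$entry_age < rng[1] - 1e-9 | cohort$entry_age + tau > rng[2] + 1e-9)
  if (length(bad))
    stop(sprintf("record %d (entry age %g, horizon %g) falls outside the hazard grid [%g, %g)",
                 bad[1L], cohort$entry_age[bad[1L]], tau[bad[1L]], rng[1], rng[2]))
  sum(absoluteRisk(cohort$entry_age, tau, r, region@baseline, region@mortality))
}

cohortRR <- function(cohort, scheme) {
  if ("rr" %in% names(cohort)) return(as.numeric(cohort$rr))
  compositeRR(cohort, scheme)
}

#' Expected/observed calibration ratio
#'
#' `E/O` with a 95% CI from the log-normal Poisson approximation on the
#' observed count: `ratio * exp(-+ 1.96 / sqrt(O))`.  With `O = 0` the
#' ratio is undefined and reported as `NA`.
#'
#' @param expected expected event count E (non-negative).
#' @param observed observed event count O (non-negative integer).
#' @return list with `ratio` and `ci` (length 2).
#' @examples
#' eoRatio(35.02, 34)$ratio   # 1.03 at 2 d.p.
#' @export
eoRatio <- function(expected, observed) {
  if (expected < 0) stop("expected count must be non-negative")
  if (observed < 0) stop("observed count must be non-negative")
  if (observed == 0) {
    message("no observed events: E/O ratio is undefined")
    return(list(ratio = NA_real_, ci = c(NA_real_, NA_real_)))
  }
  ratio <- expected / observed
  half <- exp(1.96 / sqrt(observed))
  list(ratio = ratio, ci = c(ratio / half, ratio * half))
}

#' Concordance statistic (C) for predicted risks
#'
#' Probability that a randomly chosen case has a higher predicted risk
#' than a randomly chosen non-case; ties count one half.  Computed by
#' the rank (Mann--Whitney) identity in O(n log n); the standard error
#' is Hanley--McNeil and the 95% CI `c -+ 1.96 se` is truncated to
#' `[0, 1]`.
#'
#' @param risks per-person predicted probabilities.
#' @param outcomes logical or 0/1 event indicators; at least one case
#'   and one non-case are required.
#' @return list with `c`, `se`, `ci`.
#' @examples
#' cStatistic(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$c   # 0.75
#' @export
cStatistic <- function(risks, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(risks) != length(outcomes)) stop("risks and outcomes lengths differ")
  if (anyNA(risks) || anyNA(outcomes)) stop("missing values are not allowed")
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  if (n1 == 0L || n0 == 0L)
    stop("need at least one case and one non-case to compute concordance")
  rk <- rank(risks, ties.method = "average")
  cstat <- (sum(rk[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- cstat / (2 - cstat)
  q2 <- 2 * cstat^2 / (1 + cstat)
  se <- sqrt((cstat * (1 - cstat) + (n1 - 1) * (q1 - cstat^2) +
              (n0 - 1) * (q2 - cstat^2)) / (n1 * n0))
  ci <- pmin(1, pmax(0, cstat + c(-1.96, 1.96) * se))
  list(c = cstat, se = se, ci = ci)
}

#' Crude incidence rate per 100,000 person-years
#'
#' @param nCases number of incident cases.
#' @param nPersons cohort size.
#' @param years mean follow-up in years per person.
#' @return rate per 100,000 person-years (unrounded; round at display).
#' @examples
#' crudeIncidenceRate(34, 13176, 7)   # 36.86 at 2 d.p.
#' @export
crudeIncidenceRate <- function(nCases, nPersons, years) {
  if (nCases < 0) stop("case count must be non-negative")
  if (nPersons <= 0 || years <= 0) stop("person-time must be positive")
  nCases / (nPersons * years) * 1e5
}

#' Validate a projection model on cohort follow-up data
#'
#' Computes calibration (E/O with CI) and discrimination (concordance
#' statistic) of the region model on a cohort.  Expected events use
#' each woman's realized follow-up; the risks ranked by the concordance
#' statistic are projected over a common fixed horizon (default: the
#' cohort's maximum follow-up, capped at the grid end per woman) so
#' that cases truncated at diagnosis are not artificially deflated.
#'
#' @inheritParams expectedEvents
#' @param cHorizon fixed horizon for the discrimination risks;
#'   default `max(cohort$follow_up)`.
#' @return a [ValidationResult-class].
#' @export
validateCohort <- function(cohort, region, scheme = defaultScheme(), cHorizon = NULL) {
  if (!all(c("entry_age", "follow_up", "event") %in% names(cohort)))
    stop("cohort needs columns entry_age, follow_up, event")
  if ("competing_death" %in% names(cohort) &&
      any(cohort$event == 1 & cohort$competing_death == 1))
    stop("event and competing_death cannot both be 1")
  E <- expectedEvents(cohort, region, scheme)
  O <- sum(cohort$event)
  eo <- eoRatio(E, O)

  if (is.null(cHorizon)) cHorizon <- max(cohort$follow_up)
  rng <- gridRange(region@baseline)
  tau <- pmin(cHorizon, rng[2] - cohort$entry_age)
  r <- cohortRR(cohort, scheme)
  risks <- absoluteRisk(cohort$entry_age, tau, r, region@baseline, region@mortality)
  cs <- if (O > 0 && O < nrow(cohort)) cStatistic(risks, cohort$event)
        else list(c = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_))

  new("ValidationResult", expected = E, observed = as.numeric(O),
      eoRatio = eo$ratio, eoCI = eo$ci,
      cStatistic = cs$c, cSE = cs$se, cCI = cs$ci)
}

setMethod("show", "ValidationResult", function(object) {
  cat("Cohort validation\n")
  cat(sprintf("  expected events E : %.2f\n", object@expected))
  cat(sprintf("  observed events O : %d\n", as.integer(object@observed)))
  cat(sprintf("  E/O ratio         : %.2f (95%% CI %.2f, %.2f)\n",
              object@eoRatio, object@eoCI[1], object@eoCI[2]))
  cat(sprintf("  C-statistic       : %.2f (SE %.3f; 95%% CI %.2f, %.2f)\n",
              object@cStatistic, object@cSE, object@cCI[1], object@cCI[2]))
})

#' Serialise a validation result as a report list
#'
#' @param result a [ValidationResult-class].
#' @return plain list suitable for `jsonlite::toJSON`.
#' @export
validationReport <- function(result) {
  stopifnot(is(result, "ValidationResult"))
  list(E = result@expected, O = result@observed,
       eo_ratio = result@eoRatio, eo_ci = result@eoCI,
       c = result@cStatistic, c_se = result@cSE, c_ci = result@cCI)
}
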