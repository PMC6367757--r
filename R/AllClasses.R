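#' @import methods
NULL

#' Risk-factor scheme: coded categories and their relative risks
#'
#' A `RiskFactorScheme` holds the coding scheme for a set of categorical
#' risk factors together with the relative risk (RR) attached to each
#' category.  Code 0 is always the reference category and carries RR 1;
#' an individual's composite RR is the product of her per-factor category
#' RRs (multiplicative model).
#'
#' @slot table a `data.frame` with columns `factor` (character),
#'   `code` (integer, 0-based within factor), `label` (character) and
#'   `rr` (positive numeric, 1 at code 0).
#'
#' @seealso [riskFactorScheme()], [defaultScheme()], [compositeRR()]
#' @export
setClass("RiskFactorScheme", representation(table = "data.frame"))

setValidity("RiskFactorScheme", function(object) {
  tb <- object@table
  need <- c("factor", "code", "label", "rr")
  if (!all(need %in% names(tb)))
    return(sprintf("scheme table must have columns %s", paste(need, collapse = ", ")))
  if (nrow(tb) == 0L) return("scheme table is empty")
  if (!is.numeric(tb$rr) || any(!is.finite(tb$rr)) || any(tb$rr <= 0))
    return("all relative risks must be strictly positive and finite")
  for (f in unique(tb$factor)) {
    codes <- sort(tb$code[tb$factor == f])
    if (!identical(as.integer(codes), seq_along(codes) - 1L))
      return(sprintf("factor '%s': codes must be contiguous integers 0..K-1", f))
    if (abs(tb$rr[tb$factor == f & tb$code == 0L] - 1) > 0)
      return(sprintf("factor '%s': reference code 0 must have rr exactly 1.0", f))
  }
  if (anyDuplicated(tb[c("factor", "code")]))
    return("duplicated (factor, code) rows")
  TRUE
})

#' Piecewise-constant age-specific hazard schedule
#'
#' Rates (events per person-year) assumed constant within contiguous
#' half-open age bands `[start, start + width)`.  The default grid has
#' twelve 5-year bands covering ages 25--84.
#'
#' @slot bandStart integer start (in years) of each band, ascending.
#' @slot bandWidth width of every band in years (default 5).
#' @slot rates non-negative per person-year rate for each band.
#' @slot kind one of `"incidence"`, `"competing_mortality"`, `"baseline"`.
#'
#' @seealso [hazardSchedule()], [readRateTable()], [calibrateBaseline()]
#' @export
setClass("HazardSchedule",
  representation(bandStart = "numeric", bandWidth = "numeric",
                 rates = "numeric", kind = "character"))

setValidity("HazardSchedule", function(object) {
  ks <- c("incidence", "competing_mortality", "baseline")
  if (length(object@kind) != 1L || !object@kind %in% ks)
    return(sprintf("kind must be one of %s", paste(ks, collapse = ", ")))
  if (length(object@bandWidth) != 1L || object@bandWidth <= 0)
    return("bandWidth must be a single positive number")
  n <- length(object@bandStart)
  if (n == 0L) return("at least one age band is required")
  if (length(object@rates) != n)
    return("one rate per band is required")
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    return("rates must be non-negative and finite")
  if (n > 1L) {
    gaps <- diff(object@bandStart)
    bad <- which(abs(gaps - object@bandWidth) > 1e-9)
    if (length(bad))
      return(sprintf("bands must be contiguous and non-overlapping; offending band starts at %g",
                     object@bandStart[bad[1L] + 1L]))
  }
  TRUE
})

#' Grid of projected absolute risks
#'
#' Absolute risks (proportion scale, `[0, 1]`) indexed by initial age,
#' follow-up duration and composite relative risk.  Cells whose horizon
#' would extend beyond the hazard grid are `NA` (the published layout is
#' ragged: e.g. no 30-year projection from age 70).
#'
#' @slot ages sorted initial ages (years).
#' @slot durations sorted follow-up durations (years).
#' @slot rrGrid sorted composite relative-risk values.
#' @slot risks 3-D array `[age, duration, rr]` of proportions (or `NA`).
#'
#' @seealso [buildRiskTable()], [interpolateRisk()], [readRiskTable()]
#' @export
setClass("RiskTable",
  representation(ages = "numeric", durations = "numeric",
                 rrGrid = "numeric", risks = "array"))

setValidity("RiskTable", function(object) {
  if (is.unsorted(object@ages, strictly = TRUE)) return("ages must be sorted, unique")
  if (is.unsorted(object@durations, strictly = TRUE)) return("durations must be sorted, unique")
  if (is.unsorted(object@rrGrid, strictly = TRUE)) return("rrGrid must be sorted, unique")
  d <- dim(object@risks)
  if (!identical(d, c(length(object@ages), length(object@durations), length(object@rrGrid))))
    return("risks array dimensions must match the three grids")
  v <- object@risks[!is.na(object@risks)]
  if (any(v < 0 | v > 1))
    return("risks must be proportions in [0, 1]")
  # monotone along duration and RR at fixed other coordinates (NA-tolerant)
  mono <- function(x) all(diff(x[!is.na(x)]) >= -1e-12)
  for (i in seq_along(object@ages)) {
    for (k in seq_along(object@rrGrid))
      if (!mono(object@risks[i, , k])) return("risks must be non-decreasing in duration")
    for (j in seq_along(object@durations))
      if (!mono(object@risks[i, j, ])) return("risks must be non-decreasing in relative risk")
  }
  TRUE
})

setClassUnion("RiskTableOrNULL", c("RiskTable", "NULL"))

#' Region model: rate tables plus attributable-risk calibration
#'
#' Bundles everything needed to project risk in one region: the
#' registry incidence and competing-mortality schedules, the population
#' attributable risk (AR) used to calibrate the baseline hazard, the
#' calibrated baseline itself, and (optionally) a reference risk table
#' used for interpolation lookups.  The AR is region-specific and never
#' applied silently to another region's rates.
#'
#' @slot name region label.
#' @slot incidence breast-cancer incidence [HazardSchedule-class].
#' @slot mortality non-breast-cancer mortality [HazardSchedule-class].
#' @slot attributableRisk AR in `[0, 1)`.
#' @slot baseline calibrated baseline hazard, `incidence * (1 - AR)`.
#' @slot riskTable a [RiskTable-class] for interpolation, or `NULL`.
#'
#' @seealso [regionModel()], [loadRegion()], [projectProfile()]
#' @export
setClass("RegionModel",
  representation(name = "character", incidence = "HazardSchedule",
                 mortality = "HazardSchedule", attributableRisk = "numeric",
                 baseline = "HazardSchedule", riskTable = "RiskTableOrNULL"))

setValidity("RegionModel", function(object) {
  if (length(object@attributableRisk) != 1L ||
      object@attributableRisk < 0 || object@attributableRisk >= 1)
    return("attributableRisk must be a single value in [0, 1)")
  if (object@incidence@kind != "incidence") return("incidence slot must have kind 'incidence'")
  if (object@mortality@kind != "competing_mortality")
    return("mortality slot must have kind 'competing_mortality'")
  if (object@baseline@kind != "baseline") return("baseline slot must have kind 'baseline'")
  if (!identical(object@incidence@bandStart, object@mortality@bandStart))
    return("incidence and mortality must share one age-band grid")
  TRUE
})

#' Synthetic-cohort simulation settings
#'
#' Describes a cohort-generating process with the same statistical
#' structure the projection model assumes: factor codes sampled
#' independently from marginal prevalences, composite RR multiplicative,
#' event and competing-death times from a piecewise-exponential
#' cause-specific hazard model, fixed administrative censoring.
#'
#' @slot n cohort size.
#' @slot prevalences named list (one element per scheme factor) of
#'   category probability vectors, each summing to 1.
#' @slot entryAges either `list(min=, max=)` for a uniform draw or
#'   `list(ages=, probs=)` for a categorical draw.
#' @slot horizon administrative censoring time in years.
#' @slot baseline calibrated baseline hazard [HazardSchedule-class].
#' @slot mortality competing mortality [HazardSchedule-class].
#' @slot scheme the generating [RiskFactorScheme-class].
#' @slot lossToFollowUp probability of uniform random early censoring
#'   (0 disables; default 0).
#'
#' @seealso [simulationConfig()], [simulateCohort()], [analyticAR()]
#' @export
setClass("SimulationConfig",
  representation(n = "numeric", prevalences = "list", entryAges = "list",
                 horizon = "numeric", baseline = "HazardSchedule",
                 mortality = "HazardSchedule", scheme = "RiskFactorScheme",
                 lossToFollowUp = "numeric"))

setValidity("SimulationConfig", function(object) {
  if (length(object@n) != 1L || object@n < 1) return("n must be a positive count")
  if (length(object@horizon) != 1L || object@horizon <= 0) return("horizon must be positive")
  fn <- factorNames(object@scheme)
  if (!identical(sort(names(object@prevalences)), sort(fn)))
    return("prevalences must name exactly the scheme's factors")
  for (f in fn) {
    p <- object@prevalences[[f]]
    k <- nLevels(object@scheme)[[f]]
    if (length(p) != k) return(sprintf("factor '%s': %d prevalences required", f, k))
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      return(sprintf("factor '%s': prevalences must be non-negative and sum to 1", f))
  }
  if (object@baseline@kind != "baseline") return("baseline slot must have kind 'baseline'")
  if (object@mortality@kind != "competing_mortality")
    return("mortality slot must have kind 'competing_mortality'")
  if (object@lossToFollowUp < 0 || object@lossToFollowUp > 1)
    return("lossToFollowUp must be a probability")
  ea <- object@entryAges
  if (!(all(c("min", "max") %in% names(ea)) || all(c("ages", "probs") %in% names(ea))))
    return("entryAges must be list(min=, max=) or list(ages=, probs=)")
  TRUE
})

#' Cohort validation summary
#'
#' Calibration and discrimination of the projection model on a cohort:
#' expected events E (sum of per-woman model probabilities), observed
#' events O, the E/O ratio with a log-normal Poisson 95% CI, and the
#' concordance statistic with Hanley--McNeil standard error.
#'
#' @slot expected expected event count E.
#' @slot observed observed event count O.
#' @slot eoRatio E/O (NA when O = 0).
#' @slot eoCI length-2 95% CI for E/O.
#' @slot cStatistic concordance statistic in `[0, 1]`.
#' @slot cSE its standard error.
#' @slot cCI length-2 95% CI, truncated to `[0, 1]`.
#'
#' @seealso [validateCohort()], [eoRatio()], [cStatistic()]
#' @export
setClass("ValidationResult",
  representation(expected = "numeric", observed = "numeric",
                 eoRatio = "numeric", eoCI = "numeric",
                 cStatistic = "numeric", cSE = "numeric", cCI = "numeric"))

setValidity("ValidationResult", function(object) {
  if (object@expected < 0) return("expected must be non-negative")
  if (object@observed < 0) return("observed must be non-negative")
  ok <- function(ci, x) length(ci) == 2L &&
    (is.na(x) || (ci[1] <= x + 1e-12 && x <= ci[2] + 1e-12))
  if (!ok(object@eoCI, object@eoRatio)) return("eoCI must bracket eoRatio")
  if (!is.na(object@cStatistic)) {
    if (object@cStatistic < 0 || object@cStatistic > 1)
      return("cStatistic must lie in [0, 1]")
    if (!ok(object@cCI, object@cStatistic)) return("cCI must bracket cStatistic")
  }
  TRUE
})
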