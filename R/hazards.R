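#' Construct a piecewise-constant hazard schedule
#'
#' @param bandStart ascending band start ages (years).
#' @param rates per-band rates; per person-year unless `per100k = TRUE`.
#' @param kind `"incidence"`, `"competing_mortality"` or `"baseline"`.
#' @param bandWidth band width in years (default 5).
#' @param per100k if `TRUE`, `rates` are per 100,000 person-years and
#'   are converted to per person-year internally.
#' @return a [HazardSchedule-class].
#' @examples
#' hazardSchedule(seq(25, 80, 5), rep(30, 12), "incidence", per100k = TRUE)
#' @export
hazardSchedule <- function(bandStart, rates, kind, bandWidth = 5, per100k = FALSE) {
  if (per100k) rates <- rates / 1e5
  new("HazardSchedule", bandStart = as.numeric(bandStart),
      bandWidth = as.numeric(bandWidth), rates = as.numeric(rates),
      kind = kind)
}

#' @rdname HazardSchedule-class
#' @export
setMethod("bandStarts", "HazardSchedule", function(x) x@bandStart)
#' @rdname HazardSchedule-class
#' @export
setMethod("bandWidth", "HazardSchedule", function(x) x@bandWidth)
#' @rdname HazardSchedule-class
#' @export
setMethod("rates", "HazardSchedule", function(x) x@rates)
#' @rdname HazardSchedule-class
#' @export
setMethod("hazardKind", "HazardSchedule", function(x) x@kind)
#' @rdname HazardSchedule-class
#' @export
setMethod("gridRange", "HazardSchedule", function(x)
  c(x@bandStart[1L], x@bandStart[length(x@bandStart)] + x@bandWidth))

setMethod("show", "HazardSchedule", function(object) {
  rng <- gridRange(object)
  cat(sprintf("HazardSchedule (%s): %d bands of %gy over ages [%g, %g)\n",
              object@kind, length(object@rates), object@bandWidth, rng[1], rng[2]))
  cat("  rates per 100,000 person-years:\n  ")
  cat(format(object@rates * 1e5, digits = 4), sep = " ")
  cat("\n")
})

#' Read / write an age-specific rate table
#'
#' CSV dialect: columns `age_start,age_end,rate_per_100k`, one row per
#' band; `age_end` is inclusive of its last whole year (a 25--29 row
#' covers ages `[25, 30)`).  Rows out of order are sorted with a
#' message; overlapping or gapped bands and negative rates are
#' rejected.  Rates are stored internally per person-year.
#'
#' @param path CSV path.
#' @param kind schedule kind, see [hazardSchedule()].
#' @return `readRateTable` a [HazardSchedule-class];
#'   `writeRateTable` returns `path` invisibly (round-trip identity).
#' @export
readRateTable <- function(path, kind = "incidence") {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_start", "age_end", "rate_per_100k")
  if (!all(need %in% names(tb)))
    stop(sprintf("rate table must have columns %s", paste(need, collapse = ",")))
  if (is.unsorted(tb$age_start, strictly = TRUE)) {
    message("rate-table rows out of order; sorting by age_start")
    tb <- tb[order(tb$age_start), , drop = FALSE]
  }
  if (any(tb$rate_per_100k < 0))
    stop(sprintf("negative rate in band starting at %g", tb$age_start[which(tb$rate_per_100k < 0)[1L]]))
  widths <- tb$age_end + 1 - tb$age_start
  if (any(widths <= 0)) stop("age_end must be >= age_start")
  if (length(unique(widths)) != 1L)
    stop("all bands must have equal width")
  if (nrow(tb) > 1L) {
    gap <- tb$age_start[-1L] - (tb$age_end[-nrow(tb)] + 1)
    bad <- which(gap != 0)
    if (length(bad))
      stop(sprintf("band starting at %g leaves a gap or overlap with its predecessor",
                   tb$age_start[bad[1L] + 1L]))
  }
  hazardSchedule(tb$age_start, tb$rate_per_100k, kind = kind,
                 bandWidth = widths[1L], per100k = TRUE)
}

#' @rdname readRateTable
#' @param schedule a [HazardSchedule-class].
#' @export
writeRateTable <- function(schedule, path) {
  stopifnot(is(schedule, "HazardSchedule"))
  tb <- data.frame(age_start = schedule@bandStart,
                   age_end = schedule@bandStart + schedule@bandWidth - 1,
                   rate_per_100k = schedule@rates * 1e5)
  utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bruzzi attributable risk from a case stratum distribution
#'
#' Estimates the population attributable risk from the distribution of
#' cases over risk strata and each stratum's composite relative risk:
#' `AR = 1 - sum_j rho_j / r_j`, where `rho_j` is the proportion of
#' cases in stratum j and `r_j` its relative risk.  The estimate is
#' invariant to stratum order and to merging strata with equal RR, and
#' non-decreasing in every `r_j`.
#'
#' @param rr stratum composite relative risks (positive), or a coded
#'   profile data.frame (one row per case) when `prop` is `NULL`.
#' @param prop case proportions, summing to 1 (tolerance 1e-9).  When
#'   `NULL`, `rr` is taken as individual-level case profiles and the
#'   stratum distribution is built by cross-classifying them.
#' @param scheme [RiskFactorScheme-class] used to resolve profile rows
#'   to composite RRs (individual-level mode only).
#' @return attributable risk in `[0, 1)`.
#' @examples
#' bruzziAR(rr = c(1, 2), prop = c(0.5, 0.5))   # 0.25
#' @export
bruzziAR <- function(rr, prop = NULL, scheme = defaultScheme()) {
  if (is.null(prop)) {
    stopifnot(is.data.frame(rr))
    r <- compositeRR(rr, scheme)
    agg <- tapply(rep(1L, length(r)), r, sum)
    rr <- as.numeric(names(agg))
    prop <- as.numeric(agg) / length(r)
  }
  rr <- as.numeric(rr)
  prop <- as.numeric(prop)
  if (length(rr) != length(prop)) stop("rr and prop lengths differ")
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("stratum relative risks must be positive")
  if (any(prop < 0)) stop("case proportions must be non-negative")
  if (abs(sum(prop) - 1) > 1e-9)
    stop(sprintf("case proportions must sum to 1 (got %.10f)", sum(prop)))
  1 - sum(prop / rr)
}

#' Calibrate the baseline hazard by attributable risk
#'
#' The baseline hazard is the hazard of a woman at the reference level
#' of every factor; it is obtained by multiplying each age-specific
#' incidence rate by `(1 - AR)`.
#'
#' @param incidence a [HazardSchedule-class] of kind `"incidence"`.
#' @param ar attributable risk in `[0, 1)`.
#' @return a [HazardSchedule-class] of kind `"baseline"`.
#' @examples
#' inc <- hazardSchedule(seq(25, 80, 5), rep(100, 12), "incidence", per100k = TRUE)
#' rates(calibrateBaseline(inc, 0.78)) * 1e5   # 22 per 100k in every band
#' @export
calibrateBaseline <- function(incidence, ar) {
  stopifnot(is(incidence, "HazardSchedule"))
  if (incidence@kind != "incidence")
    stop("calibrateBaseline requires a schedule of kind 'incidence'")
  if (!is.numeric(ar) || length(ar) != 1L || ar < 0 || ar >= 1)
    stop("ar must be a single value in [0, 1)")
  new("HazardSchedule", bandStart = incidence@bandStart,
      bandWidth = incidence@bandWidth,
      rates = incidence@rates * (1 - ar), kind = "baseline")
}
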