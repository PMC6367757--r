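#' Absolute risk under cause-specific competing hazards
#'
#' Probability of developing breast cancer over `[age, age + years)`
#' for a woman with composite relative risk `rr`, accounting for
#' competing (non-breast-cancer) mortality:
#' \deqn{P = \int_a^{a+\tau} r\,h_1^*(t)\,
#'   \exp\!\left(-\int_a^t [r\,h_1^*(u) + h_2(u)]\,du\right) dt}
#' where \eqn{h_1^*} is the calibrated baseline breast-cancer hazard
#' and \eqn{h_2} the competing mortality.  Both hazards are piecewise
#' constant on 5-year age bands, so the integral is evaluated in
#' closed form band by band: with total hazard
#' \eqn{\lambda_k = r h^*_{1k} + h_{2k}} on a sub-interval of length
#' \eqn{\Delta_k}, the contribution is
#' \eqn{(r h^*_{1k}/\lambda_k)\, S_k (1 - e^{-\lambda_k \Delta_k})},
#' with \eqn{S_k} the survival accumulated since `age`.
#'
#' All arguments are vectorised over queries.
#'
#' @param age initial age(s), at or above the grid start.
#' @param years projection horizon(s) in years, positive;
#'   `age + years` must not exceed the grid end.
#' @param rr composite relative risk(s), positive.
#' @param baseline [HazardSchedule-class] of kind `"baseline"`.
#' @param mortality [HazardSchedule-class] of kind
#'   `"competing_mortality"`, on the same grid.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' b <- hazardSchedule(seq(25, 80, 5), rep(100, 12), "incidence", per100k = TRUE)
#' b <- calibrateBaseline(b, 0)
#' m <- hazardSchedule(seq(25, 80, 5), rep(0, 12), "competing_mortality")
#' absoluteRisk(30, 10, 1, b, m)   # 1 - exp(-0.001 * 10)
#' @export
absoluteRisk <- function(age, years, rr, baseline, mortality) {
  riskDecomposition(age, years, rr, baseline, mortality)$event
}

#' Event / competing-death / survival decomposition
#'
#' Closed-form probabilities of the three mutually exclusive outcomes
#' over the horizon: breast cancer first, competing death first, or
#' neither.  The three sum to 1 (up to floating point), which
#' [absoluteRisk()] relies on.
#'
#' @inheritParams absoluteRisk
#' @return list of numeric vectors `event`, `competing`, `surviving`.
#' @export
riskDecomposition <- function(age, years, rr, baseline, mortality) {
  stopifnot(is(baseline, "HazardSchedule"), is(mortality, "HazardSchedule"))
  if (baseline@kind != "baseline")
    stop("baseline schedule must have kind 'baseline' (see calibrateBaseline)")
  if (mortality@kind != "competing_mortality")
    stop("mortality schedule must have kind 'competing_mortality'")
  if (!identical(baseline@bandStart, mortality@bandStart) ||
      baseline@bandWidth != mortality@bandWidth)
    stop("baseline and mortality must share one age-band grid")

  n <- max(length(age), length(years), length(rr))
  age <- rep_len(as.numeric(age), n)
  years <- rep_len(as.numeric(years), n)
  rr <- rep_len(as.numeric(rr), n)
  if (any(!is.finite(rr)) || any(rr <= 0)) stop("rr must be positive")
  if (any(years <= 0)) stop("projection horizon must be positive")
  rng <- gridRange(baseline)
  if (any(age < rng[1] - 1e-9))
    stop(sprintf("initial age %g below the hazard grid start %g", min(age), rng[1]))
  over <- which(age + years > rng[2] + 1e-9)
  if (length(over))
    stop(sprintf("projection to age %g extends beyond the hazard grid end %g",
                 max(age + years), rng[2]))

  starts <- baseline@bandStart
  ends <- starts + baseline@bandWidth
  b <- baseline@rates
  m <- mortality@rates

  S <- rep(1, n)
  P1 <- numeric(n)
  P2 <- numeric(n)
  hi0 <- age + years
  for (k in seq_along(starts)) {
    lo <- pmax(age, starts[k])
    hi <- pmin(hi0, ends[k])
    d <- pmax(0, hi - lo)
    h1 <- rr * b[k]
    lam <- h1 + m[k]
    act <- d > 0 & lam > 0
    if (any(act)) {
      q <- S[act] * (1 - exp(-lam[act] * d[act]))  # S_k - S_{k+1}
      P1[act] <- P1[act] + q * h1[act] / lam[act]
      P2[act] <- P2[act] + q * m[k] / lam[act]
      S[act] <- S[act] * exp(-lam[act] * d[act])
    }
  }
  list(event = P1, competing = P2, surviving = S)
}

#' Build a risk table over age, duration and relative-risk grids
#'
#' Evaluates [absoluteRisk()] at every grid combination.  Cells whose
#' horizon extends beyond the hazard grid (e.g. 30-year projection
#' from age 70 on a grid ending at 85) are set to `NA` with a warning,
#' matching the ragged layout of published risk tables.
#'
#' @param ages,durations,rrGrid sorted, non-empty grids.
#' @inheritParams absoluteRisk
#' @return a [RiskTable-class].
#' @export
buildRiskTable <- function(ages, durations, rrGrid, baseline, mortality) {
  if (!length(ages) || !length(durations) || !length(rrGrid))
    stop("grids must be non-empty")
  rng <- gridRange(baseline)
  risks <- array(NA_real_, dim = c(length(ages), length(durations), length(rrGrid)))
  nDropped <- 0L
  for (i in seq_along(ages)) for (j in seq_along(durations)) {
    if (ages[i] + durations[j] > rng[2] + 1e-9) { nDropped <- nDropped + 1L; next }
    risks[i, j, ] <- tryCatch(
      absoluteRisk(ages[i], durations[j], rrGrid, baseline, mortality),
      error = function(e) stop(sprintf(
        "risk-table cell (age %g, duration %g) failed: %s",
        ages[i], durations[j], conditionMessage(e))))
  }
  if (nDropped > 0L)
    warning(sprintf("%d cell(s) beyond the hazard grid end %g set to NA",
                    nDropped, rng[2]))
  new("RiskTable", ages = as.numeric(ages), durations = as.numeric(durations),
      rrGrid = as.numeric(rrGrid), risks = risks)
}

#' @rdname RiskTable-class
#' @export
setMethod("tableAges", "RiskTable", function(x) x@ages)
#' @rdname RiskTable-class
#' @export
setMethod("tableDurations", "RiskTable", function(x) x@durations)
#' @rdname RiskTable-class
#' @export
setMethod("rrGrid", "RiskTable", function(x) x@rrGrid)
#' @rdname RiskTable-class
#' @export
setMethod("riskValues", "RiskTable", function(x) x@risks)

setMethod("show", "RiskTable", function(object) {
  cat(sprintf("RiskTable: %d ages x %d durations x %d relative risks\n",
              length(object@ages), length(object@durations), length(object@rrGrid)))
  cat("  ages:", object@ages, "\n  durations:", object@durations,
      "\n  rr grid:", object@rrGrid, "\n")
  cat(sprintf("  risks (%%): %s\n", paste(
    format(roundHalfUp(100 * range(object@risks, na.rm = TRUE), 2)),
    collapse = " .. ")))
})

#' Interpolate a risk table along the relative-risk axis
#'
#' Linear interpolation between the two grid RRs bracketing `rr`, at an
#' exact (age, duration) grid cell; an exact grid RR returns the cell
#' value unchanged.  Age and duration are never interpolated: off-grid
#' queries on those axes are rejected (route them to [absoluteRisk()]
#' instead).
#'
#' @param table a [RiskTable-class].
#' @param age,years exact members of the table's age/duration grids.
#' @param rr query relative risk within the table's RR range.
#' @param extrapolate allow linear extrapolation from the outermost
#'   segment when `rr` falls outside the grid (logged; default off).
#' @return probability (proportion scale).
#' @export
interpolateRisk <- function(table, age, years, rr, extrapolate = FALSE) {
  stopifnot(is(table, "RiskTable"))
  i <- match(age, table@ages)
  j <- match(years, table@durations)
  if (is.na(i))
    stop(sprintf("age %g is not a table grid age (%s); use absoluteRisk for off-grid ages",
                 age, paste(table@ages, collapse = ", ")))
  if (is.na(j))
    stop(sprintf("duration %g is not a table grid duration (%s); use absoluteRisk for off-grid durations",
                 years, paste(table@durations, collapse = ", ")))
  g <- table@rrGrid
  if (rr < g[1L] || rr > g[length(g)]) {
    if (!extrapolate)
      stop(sprintf("rr %g outside the table grid [%g, %g]; pass extrapolate = TRUE to extend",
                   rr, g[1L], g[length(g)]))
    message(sprintf("rr %g outside the grid: extrapolating linearly", rr))
    k <- if (rr < g[1L]) 1L else length(g) - 1L
  } else {
    k <- max(1L, findInterval(rr, g, rightmost.closed = TRUE))
  }
  y1 <- table@risks[i, j, k]
  y2 <- table@risks[i, j, k + 1L]
  if (is.na(y1) || is.na(y2))
    stop(sprintf("table cell (age %g, duration %g) is empty", age, years))
  y1 + (y2 - y1) * (rr - g[k]) / (g[k + 1L] - g[k])
}

#' Read / write a risk table CSV
#'
#' Long format: columns `age,followup_years,rr,risk_pct` (percent) or
#' `risk` (proportion); missing grid combinations become `NA` cells.
#'
#' @param path CSV path.
#' @return `readRiskTable` a [RiskTable-class]; `writeRiskTable`
#'   returns `path` invisibly.
#' @export
readRiskTable <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "followup_years", "rr") %in% names(tb)))
    stop("risk-table file must have columns age, followup_years, rr")
  if ("risk_pct" %in% names(tb)) {
    vals <- tb$risk_pct / 100
  } else if ("risk" %in% names(tb)) {
    vals <- tb$risk
  } else stop("risk-table file must have a risk_pct or risk column")
  ages <- sort(unique(tb$age))
  durs <- sort(unique(tb$followup_years))
  rrs <- sort(unique(tb$rr))
  risks <- array(NA_real_, dim = c(length(ages), length(durs), length(rrs)))
  idx <- cbind(match(tb$age, ages), match(tb$followup_years, durs), match(tb$rr, rrs))
  risks[idx] <- vals
  new("RiskTable", ages = ages, durations = durs, rrGrid = rrs, risks = risks)
}

#' @rdname readRiskTable
#' @param table a [RiskTable-class].
#' @param percent write `risk_pct` (percent, default) or `risk`
#'   (proportion).
#' @export
writeRiskTable <- function(table, path, percent = TRUE) {
  stopifnot(is(table, "RiskTable"))
  grid <- expand.grid(age = table@ages, followup_years = table@durations,
                      rr = table@rrGrid, KEEP.OUT.ATTRS = FALSE)
  v <- as.vector(table@risks)
  keep <- !is.na(v)
  grid <- grid[keep, , drop = FALSE]
  v <- v[keep]
  if (percent) grid$risk_pct <- roundHalfUp(100 * v, 2) else grid$risk <- v
  grid <- grid[order(grid$age, grid$followup_years, grid$rr), , drop = FALSE]
  utils::write.csv(grid, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Round half away from zero
#'
#' Presentation rounding for percent risks (2.875 renders as 2.88,
#' not banker's 2.87).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Full projection pipeline for one risk profile
#'
#' Encodes a raw or coded profile, forms the composite RR, and projects
#' absolute risk over `[age, age + years)` with the region's calibrated
#' hazards — both exactly (closed form) and, when the region bundles a
#' reference risk table, by RR-axis interpolation of that table.
#'
#' @param profile one-row data.frame, raw or coded (see
#'   [encodeProfile()]).
#' @param age initial age in years.
#' @param years projection horizon in years.
#' @param region a [RegionModel-class].
#' @param scheme a [RiskFactorScheme-class].
#' @return list with `compositeRR`, `exactRisk`, `exactRiskPct`,
#'   `interpolatedRisk`, `interpolatedRiskPct` (interpolated entries
#'   `NA` when the region has no reference table or the cell is
#'   off-grid).
#' @export
projectProfile <- function(profile, age, years, region, scheme = defaultScheme()) {
  stopifnot(is(region, "RegionModel"))
  codes <- encodeProfile(profile, scheme = scheme)
  r <- compositeRR(codes, scheme)
  exact <- absoluteRisk(age, years, r, region@baseline, region@mortality)
  interp <- rep(NA_real_, length(r))
  if (!is.null(region@riskTable)) {
    tab <- region@riskTable
    if (age %in% tab@ages && years %in% tab@durations) {
      interp <- vapply(r, function(ri)
        interpolateRisk(tab, age, years, ri, extrapolate = FALSE), numeric(1))
    }
  }
  list(compositeRR = r,
       exactRisk = exact, exactRiskPct = roundHalfUp(100 * exact, 2),
       interpolatedRisk = interp,
       interpolatedRiskPct = roundHalfUp(100 * interp, 2))
}
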