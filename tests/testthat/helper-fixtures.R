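# Shared fixtures and independent oracles.

defaultGrid <- seq(25, 80, by = 5)

# flat schedules on the default 12-band grid (rates per person-year)
flatBaseline <- function(rate) {
  calibrateBaseline(
    hazardSchedule(defaultGrid, rep(rate, 12), "incidence"), 0)
}
flatMortality <- function(rate) {
  hazardSchedule(defaultGrid, rep(rate, 12), "competing_mortality")
}

randomSchedules <- function() {
  inc <- hazardSchedule(defaultGrid, runif(12, 0, 0.01), "incidence")
  list(baseline = calibrateBaseline(inc, runif(1, 0, 0.9)),
       mortality = hazardSchedule(defaultGrid, runif(12, 0, 0.05),
                                  "competing_mortality"))
}

# Independent quadrature oracle for the absolute-risk integral:
# integrates r*h1(t)*exp(-H(t)) numerically, with the cumulative hazard
# of the step-function rates accumulated by interval overlap (exact for
# piecewise-constant rates).
quadRisk <- function(a, tau, r, baseline, mortality) {
  starts <- bandStarts(baseline)
  ends <- starts + bandWidth(baseline)
  b <- rates(baseline)
  m <- rates(mortality)
  lamBand <- r * b + m
  H <- function(t) sum(pmax(0, pmin(t, ends) - pmax(a, starts)) * lamBand)
  h1 <- function(t) {
    k <- findInterval(t, starts)
    r * b[pmin(k, length(b))]
  }
  integrand <- function(t) h1(t) * exp(-vapply(t, H, numeric(1)))
  cuts <- sort(unique(c(a, a + tau, starts[starts > a & starts < a + tau])))
  sum(vapply(seq_len(length(cuts) - 1L), function(i)
    stats::integrate(integrand, cuts[i], cuts[i + 1L],
                     rel.tol = 1e-13, abs.tol = 1e-15,
                     subdivisions = 200L)$value, numeric(1)))
}

# Exhaustive O(n^2) pair-counting oracle for the concordance statistic.
pairwiseC <- function(risks, outcomes) {
  outcomes <- as.logical(outcomes)
  pos <- risks[outcomes]
  neg <- risks[!outcomes]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

workedExampleRaw <- function() {
  utils::read.csv(system.file("extdata", "worked_example_profile.csv",
                              package = "bcAbsRisk"))
}
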