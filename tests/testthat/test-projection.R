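test_that("absolute risk has the exponential closed form in flat cases", {
  m0 <- flatMortality(0)
  expect_identical(absoluteRisk(30, 20, 5, flatBaseline(0), m0), 0)
  # h1* = 0.001/y, no competing mortality, r = 1, 10 years
  expect_equal(absoluteRisk(30, 10, 1, flatBaseline(0.001), m0),
               1 - exp(-0.01), tolerance = 1e-12)
})

test_that("invalid queries are rejected with explicit messages", {
  b <- flatBaseline(0.001); m <- flatMortality(0.01)
  expect_error(absoluteRisk(70, 20, 1, b, m), "beyond the hazard grid end 85")
  expect_error(absoluteRisk(20, 5, 1, b, m), "below the hazard grid start")
  expect_error(absoluteRisk(30, 0, 1, b, m), "positive")
  expect_error(absoluteRisk(30, 10, -2, b, m), "positive")
  expect_error(absoluteRisk(30, 10, 1, m, m), "baseline")
  expect_error(riskDecomposition(30, 10, 1, b, flatBaseline(0.1)),
               "competing_mortality")
})

test_that("closed form matches the quadrature oracle on random schedules", {
  set.seed(101)
  for (rep in 1:60) {
    s <- randomSchedules()
    a <- runif(1, 25, 80)
    tau <- runif(1, 0.2, 85 - a)
    r <- exp(runif(1, 0, log(30)))
    expect_equal(absoluteRisk(a, tau, r, s$baseline, s$mortality),
                 quadRisk(a, tau, r, s$baseline, s$mortality),
                 tolerance = 1e-10)
  }
})

test_that("event, competing-death and survival probabilities sum to 1", {
  set.seed(202)
  for (rep in 1:40) {
    s <- randomSchedules()
    a <- runif(1, 25, 80)
    tau <- runif(1, 0.2, 85 - a)
    d <- riskDecomposition(a, tau, exp(runif(1, 0, 3)), s$baseline, s$mortality)
    expect_lt(abs(d$event + d$competing + d$surviving - 1), 1e-12)
    expect_true(all(c(d$event, d$competing, d$surviving) >= 0))
  }
})

test_that("risk is monotone in horizon and RR, bounded, and competing mortality lowers it", {
  set.seed(303)
  for (rep in 1:25) {
    s <- randomSchedules()
    a <- runif(1, 25, 60)
    tau <- sort(runif(2, 1, 85 - a - 1))
    r <- sort(exp(runif(2, 0, 3)))
    p11 <- absoluteRisk(a, tau[1], r[1], s$baseline, s$mortality)
    p21 <- absoluteRisk(a, tau[2], r[1], s$baseline, s$mortality)
    p12 <- absoluteRisk(a, tau[1], r[2], s$baseline, s$mortality)
    expect_gte(p21, p11 - 1e-15)
    expect_gte(p12, p11 - 1e-15)
    # no-competing-mortality exponential bound
    starts <- bandStarts(s$baseline); ends <- starts + 5
    cumH1 <- sum(pmax(0, pmin(a + tau[1], ends) - pmax(a, starts)) * rates(s$baseline))
    expect_lte(p11, 1 - exp(-r[1] * cumH1) + 1e-15)
    # raising h2 strictly lowers the event probability when h1* > 0
    if (p11 > 0) {
      heavier <- hazardSchedule(starts, rates(s$mortality) + 0.05,
                                "competing_mortality")
      expect_lt(absoluteRisk(a, tau[1], r[1], s$baseline, heavier), p11)
    }
  }
})

test_that("risk tables evaluate the engine cell-wise and flag off-grid cells", {
  b <- flatBaseline(0.0005)
  m0 <- flatMortality(0)
  tab <- buildRiskTable(c(30, 40), c(5, 10), c(1, 5, 10), b, m0)
  for (i in 1:2) for (j in 1:2) for (k in 1:3)
    expect_equal(riskValues(tab)[i, j, k],
                 absoluteRisk(c(30, 40)[i], c(5, 10)[j], c(1, 5, 10)[k], b, m0),
                 tolerance = 1e-15)
  # with r = 1 and no competing mortality, the cell is the cumulative
  # baseline incidence probability
  expect_equal(riskValues(tab)[1, 2, 1], 1 - exp(-0.0005 * 10), tolerance = 1e-12)
  # horizon beyond the grid end -> NA cell with a warning
  expect_warning(t2 <- buildRiskTable(c(70, 75), c(5, 20), 1, b, m0), "NA")
  expect_true(is.na(riskValues(t2)[2, 2, 1]))
  expect_false(is.na(riskValues(t2)[1, 1, 1]))
})

test_that("risk-table interpolation is linear along the RR axis only", {
  reg <- taixingSyntheticRegion()
  tab <- referenceRiskTable(reg)
  # printed cells 2.71% (RR 20) and 3.38% (RR 25) at the worked-example RR
  expect_equal(roundHalfUp(100 * interpolateRisk(tab, 30, 20, 21.23), 2), 2.87)
  # exact grid RR returns the cell unchanged
  expect_equal(interpolateRisk(tab, 30, 20, 20), 0.0271, tolerance = 1e-12)
  # midpoint of a segment is the arithmetic mean of the two cells
  expect_equal(interpolateRisk(tab, 30, 20, 22.5), (0.0271 + 0.0338) / 2,
               tolerance = 1e-12)
  # off-grid age/duration rejected; RR outside the grid gated by extrapolate
  expect_error(interpolateRisk(tab, 31, 20, 10), "not a table grid age")
  expect_error(interpolateRisk(tab, 30, 15, 10), "not a table grid duration")
  expect_error(interpolateRisk(tab, 30, 20, 30), "outside the table grid")
  expect_message(ex <- interpolateRisk(tab, 30, 20, 30, extrapolate = TRUE),
                 "extrapolating")
  expect_equal(ex, (0.0338 + (0.0338 - 0.0271) * (30 - 25) / 5), tolerance = 1e-12)
  # empty ragged cell
  expect_error(interpolateRisk(tab, 70, 30, 10), "empty")
})

test_that("risk tables round-trip through the long CSV dialect", {
  b <- flatBaseline(0.0004); m <- flatMortality(0.002)
  tab <- buildRiskTable(c(30, 50), c(5, 10), c(1, 10), b, m)
  path <- withr::local_tempfile(fileext = ".csv")
  writeRiskTable(tab, path, percent = FALSE)
  back <- readRiskTable(path)
  expect_equal(riskValues(back), riskValues(tab), tolerance = 1e-12)
  expect_equal(rrGrid(back), c(1, 10))
})

test_that("percent rendering rounds half away from zero", {
  expect_identical(roundHalfUp(2.875, 2), 2.88)
  expect_identical(roundHalfUp(2.8748, 2), 2.87)
  expect_identical(roundHalfUp(-2.875, 2), -2.88)
})

test_that("projectProfile runs the full pipeline on the worked example", {
  reg <- taixingSyntheticRegion()
  res <- projectProfile(workedExampleRaw(), 30, 20, reg)
  expect_equal(roundHalfUp(res$compositeRR, 2), 21.23)
  expect_equal(res$interpolatedRiskPct, 2.87)
  expect_equal(res$exactRisk,
               absoluteRisk(30, 20, res$compositeRR,
                            baselineHazard(reg), competingMortality(reg)),
               tolerance = 1e-15)
  # vanishing horizon: risk tends to zero
  tiny <- projectProfile(workedExampleRaw(), 30, 1e-6, reg)
  expect_lt(tiny$exactRisk, 1e-6)
  # off-grid (age, duration) leaves the interpolated entry NA
  off <- projectProfile(workedExampleRaw(), 33, 20, reg)
  expect_true(is.na(off$interpolatedRisk))
  expect_false(is.na(off$exactRisk))
})
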