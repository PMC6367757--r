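test_that("the bundled scheme has six factors with reference RR 1", {
  sc <- defaultScheme()
  expect_setequal(factorNames(sc),
                  c("abortions", "age_first_birth", "benign_disease",
                    "bmi", "family_history", "satisfaction"))
  for (f in factorNames(sc)) {
    rr <- relativeRisks(sc, f)
    expect_identical(unname(rr[1]), 1)
    expect_true(all(rr > 0 & is.finite(rr)))
  }
  expect_equal(unname(relativeRisks(sc, "abortions")), c(1, 2.512, 6.313))
  expect_equal(unname(relativeRisks(sc, "benign_disease")), c(1, 4.255))
})

test_that("scheme invariants are enforced", {
  bad <- data.frame(factor = c("f", "f"), code = 0:1, label = c("a", "b"),
                    rr = c(1.2, 2))
  expect_error(riskFactorScheme(bad), "code 0")
  bad$rr <- c(1, -2)
  expect_error(riskFactorScheme(bad), "positive")
  bad2 <- data.frame(factor = c("f", "f"), code = c(0, 2),
                     label = c("a", "b"), rr = c(1, 2))
  expect_error(riskFactorScheme(bad2), "contiguous")
})

test_that("scheme CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeScheme(defaultScheme(), path)
  expect_equal(readScheme(path)@table, defaultScheme()@table)
})

test_that("raw measurements encode to the documented categories", {
  base <- data.frame(n_abortions = 0, age_first_birth = 22,
                     benign_breast_disease = 0, height_m = 1.6,
                     weight_kg = 20 * 1.6^2, family_history = 0,
                     satisfaction_1 = 1, satisfaction_2 = 1,
                     satisfaction_3 = 1, satisfaction_4 = 1,
                     satisfaction_5 = 1, satisfaction_6 = 1)
  expect_true(all(encodeProfile(base) == 0))          # reference everywhere

  # BMI 27 falls in the overweight band [24, 28)
  bmi27 <- base; bmi27$weight_kg <- 27 * 1.6^2
  expect_identical(encodeProfile(bmi27)$bmi, 1L)

  # band edges: 23.99 / 24 / 27.95 / 28 (height 1 m makes BMI = weight)
  for (case in list(c(23.99, 0L), c(24, 1L), c(27.95, 1L), c(28, 2L))) {
    x <- base; x$height_m <- 1; x$weight_kg <- case[1]
    expect_identical(encodeProfile(x)$bmi, as.integer(case[2]))
  }

  # abortions 0 / 1-2 / >=3 and first live birth <25 / 25-29 / >=30
  ab <- base; ab$n_abortions <- 2
  expect_identical(encodeProfile(ab)$abortions, 1L)
  ab$n_abortions <- 3
  expect_identical(encodeProfile(ab)$abortions, 2L)
  fb <- base; fb$age_first_birth <- 29
  expect_identical(encodeProfile(fb)$age_first_birth, 1L)
  fb$age_first_birth <- 30
  expect_identical(encodeProfile(fb)$age_first_birth, 2L)
})

test_that("life-satisfaction code flips exactly at a total of 13", {
  base <- data.frame(n_abortions = 0, age_first_birth = 22,
                     benign_breast_disease = 0, height_m = 1.6,
                     weight_kg = 55, family_history = 0)
  sat <- function(items) {
    x <- cbind(base, as.data.frame(as.list(
      stats::setNames(items, paste0("satisfaction_", 1:6)))))
    encodeProfile(x)$satisfaction
  }
  expect_identical(sat(c(3, 2, 2, 2, 2, 2)), 1L)  # total 13 -> unsatisfied
  expect_identical(sat(c(2, 2, 2, 2, 2, 2)), 0L)  # total 12 -> satisfied
})

test_that("invalid raw measurements are rejected", {
  base <- workedExampleRaw()
  x <- base; x$satisfaction_3 <- NA
  expect_error(encodeProfile(x), "satisfaction")
  x <- base; x$satisfaction_3 <- 6
  expect_error(encodeProfile(x), "1..5")
  x <- base; x$n_abortions <- -1
  expect_error(encodeProfile(x), "non-negative")
  x <- base; x$height_m <- 0
  expect_error(encodeProfile(x), "height")
  x <- base; x$height_m <- NULL
  expect_error(encodeProfile(x), "lack")
})

test_that("nulliparous women get the configured code with a message", {
  x <- workedExampleRaw()
  x$age_first_birth <- NA
  expect_message(codes <- encodeProfile(x), "nulliparous")
  expect_identical(codes$age_first_birth, 0L)
  expect_message(codes2 <- encodeProfile(x, nulliparousCode = 2L), "nulliparous")
  expect_identical(codes2$age_first_birth, 2L)
})

test_that("re-encoding an already-coded profile is the identity", {
  codes <- encodeProfile(workedExampleRaw())
  expect_identical(encodeProfile(codes), codes)
})

test_that("composite RR multiplies category relative risks", {
  sc <- defaultScheme()
  ref <- data.frame(abortions = 0L, age_first_birth = 0L, benign_disease = 0L,
                    bmi = 0L, family_history = 0L, satisfaction = 0L)
  expect_identical(compositeRR(ref, sc), 1)

  # worked-example profile: 2.512 * 1.895 * 1 * 1.372 * 3.250 * 1
  woman <- ref
  woman[c("abortions", "age_first_birth", "bmi", "family_history")] <- 1L
  expect_equal(round(compositeRR(woman, sc), 2), 21.23)

  # hand product of two non-reference categories: 6.313 * 4.255
  two <- ref; two$abortions <- 2L; two$benign_disease <- 1L
  expect_equal(compositeRR(two, sc), 6.313 * 4.255, tolerance = 1e-12)
  expect_equal(round(compositeRR(two, sc), 2), 26.86)
})

test_that("composite RR is multiplicative and order-invariant", {
  sc <- defaultScheme()
  set.seed(7)
  lv <- nLevels(sc)
  for (rep in 1:20) {
    codes <- as.data.frame(lapply(lv, function(k) sample.int(k, 1) - 1L))
    r0 <- compositeRR(codes, sc)
    expect_gte(r0, 1)                                   # all non-reference RRs > 1
    f <- sample(factorNames(sc), 1)
    newCode <- sample.int(lv[[f]], 1) - 1L
    rrF <- unname(relativeRisks(sc, f))
    codes2 <- codes; codes2[[f]] <- newCode
    expect_equal(compositeRR(codes2, sc),
                 r0 * rrF[newCode + 1] / rrF[codes[[f]] + 1],
                 tolerance = 1e-12)
    shuffled <- codes[sample(names(codes))]
    expect_identical(compositeRR(shuffled, sc), r0)     # factor order irrelevant
  }
})

test_that("out-of-range codes are rejected", {
  sc <- defaultScheme()
  bad <- data.frame(abortions = 3L, age_first_birth = 0L, benign_disease = 0L,
                    bmi = 0L, family_history = 0L, satisfaction = 0L)
  expect_error(compositeRR(bad, sc), "out of range")
  expect_error(compositeRR(bad["abortions"], sc), "lacks")
})
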