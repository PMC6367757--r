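#' Construct a simulation configuration
#'
#' @param n cohort size.
#' @param prevalences named list of per-factor category probability
#'   vectors (names = scheme factors, each summing to 1).
#' @param entryAges `list(min=, max=)` (uniform) or
#'   `list(ages=, probs=)` (categorical).
#' @param horizon administrative censoring time in years.
#' @param baseline,mortality [HazardSchedule-class] objects (kinds
#'   `"baseline"` and `"competing_mortality"`).
#' @param scheme generating [RiskFactorScheme-class].
#' @param lossToFollowUp probability of uniform early censoring
#'   (default 0, i.e. administrative censoring only).
#' @return a [SimulationConfig-class].
#' @seealso [taixingSimulationConfig()] for the bundled defaults.
#' @export
simulationConfig <- function(n, prevalences, entryAges, horizon,
                             baseline, mortality, scheme = defaultScheme(),
                             lossToFollowUp = 0) {
  new("SimulationConfig", n = as.numeric(n), prevalences = prevalences,
      entryAges = entryAges, horizon = as.numeric(horizon),
      baseline = baseline, mortality = mortality, scheme = scheme,
      lossToFollowUp = as.numeric(lossToFollowUp))
}

#' Marginal factor prevalences of the reference cohort population
#'
#' Category proportions among cancer-free cohort women (n = 13,142)
#' for the six model factors, used as the simulator's default
#' marginals: e.g. positive family history 0.68%, BMI >= 28 3.14%.
#'
#' @return named list of probability vectors.
#' @export
cohortPrevalences <- function() {
  norm <- function(x) x / sum(x)
  list(
    abortions       = norm(c(9612, 3210, 320)),
    age_first_birth = norm(c(9853, 3138, 151)),
    benign_disease  = norm(c(13142 - 46, 46)),
    bmi             = norm(c(9039, 3690, 413)),
    family_history  = norm(c(13142 - 90, 90)),
    satisfaction    = norm(c(13142 - 6907, 6907)))
}

#' Default Taixing-like simulation configuration
#'
#' Emulates the validation cohort's study conditions: 13,176 women,
#' entry ages uniform on [25, 70), 7 years of administrative follow-up,
#' marginal factor prevalences of the cohort's cancer-free women, and
#' the bundled synthetic region rates calibrated with AR 0.78.
#'
#' @param n cohort size (default 13176).
#' @param region a [RegionModel-class]; default [taixingSyntheticRegion()].
#' @param ... further arguments to [simulationConfig()].
#' @return a [SimulationConfig-class].
#' @export
taixingSimulationConfig <- function(n = 13176, region = taixingSyntheticRegion(), ...) {
  simulationConfig(n = n, prevalences = cohortPrevalences(),
                   entryAges = list(min = 25, max = 70), horizon = 7,
                   baseline = region@baseline, mortality = region@mortality,
                   scheme = defaultScheme(), ...)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: n = %d, horizon = %gy, loss to follow-up %g%%\n",
              as.integer(object@n), object@horizon, 100 * object@lossToFollowUp))
  ea <- object@entryAges
  if (!is.null(ea$min)) cat(sprintf("  entry ages uniform on [%g, %g)\n", ea$min, ea$max))
  else cat("  entry ages categorical over", ea$ages, "\n")
  cat("  factors:", paste(names(object@prevalences), collapse = ", "), "\n")
})

#' Simulate a cohort from the cause-specific hazard model
#'
#' For each woman: factor codes are drawn independently from the
#' configured marginal prevalences; her composite RR multiplies the
#' baseline breast-cancer hazard; the first event time is drawn from
#' the piecewise-exponential model with total hazard
#' `rr * h1(t) + h2(t)` from her entry age, and its cause is breast
#' cancer with probability `rr*h1 / (rr*h1 + h2)` at that time (latent
#' cause-specific construction); administrative censoring applies at
#' the configured horizon.  Identical seeds give identical cohorts.
#'
#' @param config a [SimulationConfig-class].
#' @param seed integer RNG seed (`NULL` uses the current RNG state).
#' @return data.frame with columns `entry_age`, `follow_up`, `event`,
#'   `competing_death`, `rr` and one code column per factor — the
#'   cohort CSV dialect consumed by [validateCohort()].
#' @export
simulateCohort <- function(config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(config@n)
  grid <- config@baseline
  rng <- gridRange(grid)

  ea <- config@entryAges
  age <- if (!is.null(ea$min)) stats::runif(n, ea$min, ea$max)
         else sample(ea$ages, n, replace = TRUE, prob = ea$probs)
  if (any(age + config@horizon > rng[2] + 1e-9))
    stop(sprintf("hazard grid ends at %g: cannot follow entry age %g for %g years",
                 rng[2], max(age), config@horizon))

  codes <- sampleCodes(n, config@prevalences)
  r <- compositeRR(codes, config@scheme)

  starts <- grid@bandStart
  ends <- starts + grid@bandWidth
  b <- grid@rates
  m <- config@mortality@rates

  target <- stats::rexp(n)            # unit-exponential total-hazard target
  cum <- numeric(n)
  t_event <- rep(NA_real_, n)
  lam_at <- numeric(n)
  h1_at <- numeric(n)
  hi0 <- age + config@horizon
  for (k in seq_along(starts)) {
    lo <- pmax(age, starts[k])
    hi <- pmin(hi0, ends[k])
    d <- pmax(0, hi - lo)
    h1 <- r * b[k]
    lam <- h1 + m[k]
    H <- lam * d
    hit <- is.na(t_event) & d > 0 & lam > 0 & target < cum + H
    if (any(hit)) {
      t_event[hit] <- (lo[hit] - age[hit]) + (target[hit] - cum[hit]) / lam[hit]
      lam_at[hit] <- lam[hit]
      h1_at[hit] <- h1[hit]
    }
    cum <- cum + H
  }

  follow <- ifelse(is.na(t_event), config@horizon, t_event)
  isEvent <- !is.na(t_event)
  isBC <- isEvent & (stats::runif(n) < ifelse(isEvent, h1_at / lam_at, 0))

  if (config@lossToFollowUp > 0) {    # optional uniform random early censoring
    lost <- stats::runif(n) < config@lossToFollowUp
    t_cens <- stats::runif(n, 0, config@horizon)
    cens <- lost & t_cens < follow
    follow[cens] <- t_cens[cens]
    isEvent[cens] <- FALSE
    isBC[cens] <- FALSE
  }

  out <- data.frame(entry_age = age, follow_up = follow,
                    event = as.integer(isBC),
                    competing_death = as.integer(isEvent & !isBC),
                    rr = r)
  cbind(out, codes)
}

sampleCodes <- function(n, prevalences) {
  codes <- lapply(prevalences, function(p)
    sample.int(length(p), n, replace = TRUE, prob = p) - 1L)
  as.data.frame(codes)
}

#' Sample case risk-factor profiles
#'
#' Draws profiles from the case population implied by the configured
#' marginals and relative risks: stratum j (a full cross-classification
#' of the factors) is drawn with probability proportional to
#' `p_j * r_j`, the case-distribution identity underlying Bruzzi's
#' attributable-risk estimator.
#'
#' @param n number of cases.
#' @param config a [SimulationConfig-class].
#' @param seed integer RNG seed.
#' @return data.frame of coded case profiles.
#' @export
simulateCases <- function(n, config, seed = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  if (!is.null(seed)) set.seed(seed)
  st <- enumerateStrata(config@prevalences, config@scheme)
  idx <- sample.int(nrow(st$codes), n, replace = TRUE, prob = st$p * st$r)
  st$codes[idx, , drop = FALSE]
}

enumerateStrata <- function(prevalences, scheme) {
  lv <- lapply(prevalences, function(p) seq_along(p) - 1L)
  codes <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE)
  p <- rep(1, nrow(codes))
  for (f in names(prevalences)) p <- p * prevalences[[f]][codes[[f]] + 1L]
  list(codes = codes, p = p, r = compositeRR(codes, scheme))
}

#' Analytic attributable risk of a simulated population
#'
#' Ground truth for Bruzzi-AR recovery: enumerates all factor
#' combinations (216 for the default scheme), with joint probability
#' the product of marginals, and evaluates
#' `AR = 1 - sum_j p_j / sum_j p_j r_j`.
#'
#' @param config a [SimulationConfig-class].
#' @return attributable risk in `[0, 1)`.
#' @export
analyticAR <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  st <- enumerateStrata(config@prevalences, config@scheme)
  1 - sum(st$p) / sum(st$p * st$r)
}

#' Read / write the cohort CSV dialect
#'
#' Columns `entry_age,follow_up,event,competing_death` plus factor code
#' columns (and optionally `rr`).
#'
#' @param path CSV path.
#' @param cohort cohort data.frame.
#' @return `readCohort` the data.frame; `writeCohort` returns `path`
#'   invisibly.
#' @export
readCohort <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("entry_age", "follow_up", "event")
  if (!all(need %in% names(tb)))
    stop(sprintf("cohort file must have columns %s", paste(need, collapse = ",")))
  tb
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a simulation configuration file
#'
#' YAML/JSON with fields `cohort_size`, `horizon`, `entry_ages` (`min`/`max` or
#' `ages`/`probs`), `prevalences` (map factor -> probability vector),
#' `region` (path to a region file, resolved relative to the config)
#' and optionally `loss_to_follow_up` and `seed`.
#'
#' @param path config file path.
#' @return list with elements `config` (a [SimulationConfig-class])
#'   and `seed` (may be `NULL`).
#' @export
loadSimulationConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("simulation config '%s' does not exist", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::fromJSON(path)
         else yaml::read_yaml(path)
  need <- c("cohort_size", "horizon", "entry_ages", "prevalences", "region")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop(sprintf("simulation config lacks field(s): %s", paste(missing, collapse = ", ")))
  dir <- dirname(normalizePath(path))
  rpath <- if (file.exists(cfg$region)) cfg$region else file.path(dir, cfg$region)
  region <- loadRegion(rpath)
  prev <- lapply(cfg$prevalences, function(p) { p <- as.numeric(p); p / sum(p) })
  config <- simulationConfig(
    n = cfg$cohort_size, prevalences = prev, entryAges = cfg$entry_ages,
    horizon = cfg$horizon, baseline = region@baseline,
    mortality = region@mortality, scheme = defaultScheme(),
    lossToFollowUp = if (is.null(cfg$loss_to_follow_up)) 0 else cfg$loss_to_follow_up)
  list(config = config, seed = cfg$seed)
}
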