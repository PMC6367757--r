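#' Encode raw questionnaire measurements into factor codes
#'
#' Applies the model's category cut-points to raw measurements:
#' \itemize{
#'   \item BMI = weight (kg) / height (m)^2, coded 0/1/2 by
#'     `< 24`, `[24, 28)`, `>= 28`;
#'   \item number of abortions coded 0 / 1--2 / >= 3 as 0/1/2;
#'   \item age at first live birth `< 25` / 25--29 / `>= 30` as 0/1/2;
#'   \item life-satisfaction total = sum of the six 1--5 items
#'     (housing, income, health, marriage, medical care, neighbours),
#'     coded 1 iff total >= 13;
#'   \item benign breast disease history and family history as 0/1.
#' }
#'
#' A data.frame that already carries the scheme's code columns is
#' validated and returned unchanged, so encoding is idempotent.
#'
#' @param raw data.frame of raw measurements, one row per person, with
#'   columns `n_abortions`, `age_first_birth` (years; `NA` for
#'   nulliparous women), `benign_breast_disease` (0/1 or logical),
#'   `height_m`, `weight_kg`, `family_history` (0/1 or logical) and
#'   `satisfaction_1` .. `satisfaction_6` (each in 1..5).
#' @param scheme a [RiskFactorScheme-class]; codes are validated
#'   against it.
#' @param nulliparousCode age-at-first-live-birth code assigned to
#'   nulliparous women (`NA` age).  The reference code 0 is the
#'   default; a message flags its use since the choice is a modelling
#'   convention, not a measurement.
#' @return data.frame with one integer code column per scheme factor.
#' @examples
#' raw <- data.frame(n_abortions = 1, age_first_live_birth = 27,
#'   benign_breast_disease = 0, height_m = 1.6, weight_kg = 27 * 1.6^2,
#'   family_history = 1, satisfaction_1 = 1, satisfaction_2 = 1,
#'   satisfaction_3 = 1, satisfaction_4 = 1, satisfaction_5 = 1,
#'   satisfaction_6 = 2)
#' names(raw)[2] <- "age_first_birth"
#' encodeProfile(raw)
#' @export
encodeProfile <- function(raw, scheme = defaultScheme(), nulliparousCode = 0L) {
  stopifnot(is(scheme, "RiskFactorScheme"))
  raw <- as.data.frame(raw)
  fn <- factorNames(scheme)
  if (all(fn %in% names(raw))) {           # already coded: validate, return
    codes <- raw[fn]
    compositeRR(codes, scheme)             # raises on out-of-range codes
    codes[] <- lapply(codes, as.integer)
    return(codes)
  }

  need <- c("n_abortions", "age_first_birth", "benign_breast_disease",
            "height_m", "weight_kg", "family_history",
            paste0("satisfaction_", 1:6))
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop(sprintf("raw measurements lack column(s): %s", paste(missing, collapse = ", ")))

  n_ab <- raw$n_abortions
  if (any(is.na(n_ab) | n_ab < 0))
    stop("n_abortions must be a non-negative count")
  h <- raw$height_m
  if (any(is.na(h) | h <= 0)) stop("height_m must be positive")
  w <- raw$weight_kg
  if (any(is.na(w) | w <= 0)) stop("weight_kg must be positive")
  sat <- as.matrix(raw[paste0("satisfaction_", 1:6)])
  if (any(is.na(sat)))
    stop("missing life-satisfaction item; all six items are required")
  if (any(!sat %in% 1:5))
    stop("life-satisfaction items must be integers in 1..5")

  bmi <- w / h^2
  afb <- raw$age_first_birth
  nullip <- is.na(afb)
  if (any(nullip)) {
    message(sprintf(
      "%d nulliparous record(s): assigning age-at-first-live-birth code %d",
      sum(nullip), nulliparousCode))
  }
  afbCode <- ifelse(nullip, as.integer(nulliparousCode),
                    cutCode(afb, c(25, 30)))

  codes <- data.frame(
    abortions       = cutCode(n_ab, c(1, 3)),
    age_first_birth = as.integer(afbCode),
    benign_disease  = as.integer(as.logical(raw$benign_breast_disease)),
    bmi             = cutCode(bmi, c(24, 28)),
    family_history  = as.integer(as.logical(raw$family_history)),
    satisfaction    = as.integer(rowSums(sat) >= 13))
  compositeRR(codes, scheme)               # validates against the scheme
  codes
}

# code 0 below cuts[1], 1 in [cuts[1], cuts[2]), 2 at/above cuts[2]
cutCode <- function(x, cuts) {
  as.integer((x >= cuts[1]) + (x >= cuts[2]))
}

#' Read profiles from CSV (raw or coded dialect)
#'
#' @param path CSV path.
#' @param coded `TRUE` if the file carries pre-coded factor columns,
#'   `FALSE` for raw measurement columns (see [encodeProfile()]).
#' @param scheme a [RiskFactorScheme-class].
#' @param ... passed to [encodeProfile()].
#' @return data.frame of factor codes.
#' @export
readProfiles <- function(path, coded = TRUE, scheme = defaultScheme(), ...) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (coded) {
    fn <- factorNames(scheme)
    missing <- setdiff(fn, names(raw))
    if (length(missing))
      stop(sprintf("coded profile file lacks column(s): %s",
                   paste(missing, collapse = ", ")))
  } else {
    raw <- raw[setdiff(names(raw), factorNames(scheme))]
  }
  encodeProfile(raw, scheme = scheme, ...)
}
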