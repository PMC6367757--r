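#' Construct a risk-factor scheme
#'
#' @param table data.frame with columns `factor`, `code`, `label`, `rr`.
#' @return a [RiskFactorScheme-class] object.
#' @examples
#' sc <- riskFactorScheme(data.frame(
#'   factor = c("smoking", "smoking"), code = 0:1,
#'   label = c("never", "ever"), rr = c(1, 1.8)))
#' compositeRR(data.frame(smoking = 1L), sc)
#' @export
riskFactorScheme <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  table$factor <- as.character(table$factor)
  table$code <- as.integer(table$code)
  table$label <- as.character(table$label)
  table$rr <- as.numeric(table$rr)
  table <- table[order(match(table$factor, unique(table$factor)), table$code), , drop = FALSE]
  rownames(table) <- NULL
  new("RiskFactorScheme", table = table)
}

#' The bundled six-factor scheme
#'
#' Category codings and multivariate relative risks for the six
#' questionnaire factors of the Han Chinese breast-cancer model:
#' number of abortions, age at first live birth, benign breast disease
#' history, BMI, breast-cancer family history, and life-satisfaction
#' score.  Code 0 is the reference category of every factor.
#'
#' @return a [RiskFactorScheme-class] with six factors.
#' @examples
#' defaultScheme()
#' @export
defaultScheme <- function() {
  riskFactorScheme(data.frame(
    factor = c(rep("abortions", 3), rep("age_first_birth", 3),
               rep("benign_disease", 2), rep("bmi", 3),
               rep("family_history", 2), rep("satisfaction", 2)),
    code = c(0:2, 0:2, 0:1, 0:2, 0:1, 0:1),
    label = c("0", "1-2", ">=3",
              "<25", "25-29", ">=30",
              "no", "yes",
              "<24", "24-27.9", ">=28",
              "no", "yes",
              "<13", ">=13"),
    rr = c(1, 2.512, 6.313,
           1, 1.895, 3.589,
           1, 4.255,
           1, 1.372, 1.882,
           1, 3.250,
           1, 2.424),
    stringsAsFactors = FALSE))
}

#' Read / write a scheme CSV
#'
#' CSV dialect: columns `factor,code,label,rr`, one row per category;
#' reference rows (code 0) must have `rr = 1`.
#'
#' @param path file path.
#' @return `readScheme` returns a [RiskFactorScheme-class];
#'   `writeScheme` returns `path` invisibly.
#' @export
readScheme <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  riskFactorScheme(tb)
}

#' @rdname readScheme
#' @param scheme a [RiskFactorScheme-class].
#' @export
writeScheme <- function(scheme, path) {
  stopifnot(is(scheme, "RiskFactorScheme"))
  utils::write.csv(scheme@table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname RiskFactorScheme-class
#' @export
setMethod("factorNames", "RiskFactorScheme", function(x) unique(x@table$factor))

#' @rdname RiskFactorScheme-class
#' @export
setMethod("nLevels", "RiskFactorScheme", function(x) {
  tb <- x@table
  out <- vapply(unique(tb$factor), function(f) sum(tb$factor == f), integer(1))
  as.list(out)
})

#' @rdname RiskFactorScheme-class
#' @export
setMethod("relativeRisks", "RiskFactorScheme", function(x, factor) {
  tb <- x@table[x@table$factor == factor, , drop = FALSE]
  if (nrow(tb) == 0L) stop(sprintf("unknown factor '%s'", factor))
  stats::setNames(tb$rr[order(tb$code)], tb$label[order(tb$code)])
})

setMethod("show", "RiskFactorScheme", function(object) {
  cat(sprintf("RiskFactorScheme with %d factors, %d categories\n",
              length(factorNames(object)), nrow(object@table)))
  print(object@table, row.names = FALSE)
})

#' Composite relative risk of coded profiles
#'
#' Multiplies the per-factor category relative risks of each profile
#' (multiplicative model); the all-reference profile has composite RR 1.
#' The result does not depend on factor order.
#'
#' @param profiles data.frame with one integer code column per scheme
#'   factor (extra columns ignored), one row per person; or a named
#'   vector/list of codes for a single person.
#' @param scheme a [RiskFactorScheme-class].
#' @return numeric vector of composite relative risks.
#' @examples
#' sc <- defaultScheme()
#' compositeRR(data.frame(abortions = 1L, age_first_birth = 1L,
#'   benign_disease = 0L, bmi = 1L, family_history = 1L,
#'   satisfaction = 0L), sc)
#' @export
compositeRR <- function(profiles, scheme) {
  stopifnot(is(scheme, "RiskFactorScheme"))
  if (!is.data.frame(profiles)) profiles <- as.data.frame(as.list(profiles))
  fn <- factorNames(scheme)
  missing <- setdiff(fn, names(profiles))
  if (length(missing))
    stop(sprintf("profile lacks factor column(s): %s", paste(missing, collapse = ", ")))
  r <- rep(1, nrow(profiles))
  tb <- scheme@table
  for (f in fn) {
    code <- as.integer(profiles[[f]])
    kmax <- sum(tb$factor == f) - 1L
    bad <- which(is.na(code) | code < 0L | code > kmax)
    if (length(bad))
      stop(sprintf("factor '%s': code out of range 0..%d in row %d", f, kmax, bad[1L]))
    rr <- tb$rr[tb$factor == f][order(tb$code[tb$factor == f])]
    r <- r * rr[code + 1L]
  }
  r
}
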