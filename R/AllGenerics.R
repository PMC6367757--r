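#' @rdname RiskFactorScheme-class
#' @param x a scheme object.
#' @export
setGeneric("factorNames", function(x) standardGeneric("factorNames"))

#' @rdname RiskFactorScheme-class
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname RiskFactorScheme-class
#' @param factor factor name.
#' @export
setGeneric("relativeRisks", function(x, factor) standardGeneric("relativeRisks"))

#' @rdname HazardSchedule-class
#' @param x a schedule object.
#' @export
setGeneric("bandStarts", function(x) standardGeneric("bandStarts"))

#' @rdname HazardSchedule-class
#' @export
setGeneric("bandWidth", function(x) standardGeneric("bandWidth"))

#' @rdname HazardSchedule-class
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname HazardSchedule-class
#' @export
setGeneric("hazardKind", function(x) standardGeneric("hazardKind"))

#' @rdname HazardSchedule-class
#' @export
setGeneric("gridRange", function(x) standardGeneric("gridRange"))

#' @rdname RiskTable-class
#' @param x a risk-table object.
#' @export
setGeneric("tableAges", function(x) standardGeneric("tableAges"))

#' @rdname RiskTable-class
#' @export
setGeneric("tableDurations", function(x) standardGeneric("tableDurations"))

#' @rdname RiskTable-class
#' @export
setGeneric("rrGrid", function(x) standardGeneric("rrGrid"))

#' @rdname RiskTable-class
#' @export
setGeneric("riskValues", function(x) standardGeneric("riskValues"))

#' @rdname RegionModel-class
#' @param x a region-model object.
#' @export
setGeneric("regionName", function(x) standardGeneric("regionName"))

#' @rdname RegionModel-class
#' @export
setGeneric("attributableRisk", function(x) standardGeneric("attributableRisk"))

#' @rdname RegionModel-class
#' @export
setGeneric("baselineHazard", function(x) standardGeneric("baselineHazard"))

#' @rdname RegionModel-class
#' @export
setGeneric("competingMortality", function(x) standardGeneric("competingMortality"))

#' @rdname RegionModel-class
#' @export
setGeneric("referenceRiskTable", function(x) standardGeneric("referenceRiskTable"))
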