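#' Sample identifiers
#'
#' @param x a ScoreMatrix, LabelTable or PredictionSetTable.
#' @return character vector of sample ids.
#' @name sampleIds
NULL

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ScoreMatrix", function(x) rownames(x@scores))
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "LabelTable", function(x) x@sampleIds)
#' @rdname sampleIds
#' @export
setMethod("sampleIds", "PredictionSetTable", function(x) x@sampleIds)

#' Class names
#'
#' @param x a ScoreMatrix, CalibratedModel or SimulationSpec.
#' @return character vector of class names.
#' @name classNames
NULL

#' @rdname classNames
#' @export
setMethod("classNames", "ScoreMatrix", function(x) colnames(x@scores))
#' @rdname classNames
#' @export
setMethod("classNames", "CalibratedModel", function(x) x@classNames)
#' @rdname classNames
#' @export
setMethod("classNames", "SimulationSpec", function(x) x@classNames)

#' Score matrix values
#'
#' @param x a ScoreMatrix.
#' @return the underlying numeric matrix (samples x classes).
#' @name scores
NULL

#' @rdname scores
#' @export
setMethod("scores", "ScoreMatrix", function(x) x@scores)

#' Per-sample label sets
#'
#' @param x a LabelTable.
#' @return named list of character vectors (empty vector = unknown subtype).
#' @name labelSets
NULL

#' @rdname labelSets
#' @export
setMethod("labelSets", "LabelTable", function(x) {
  structure(x@labels, names = x@sampleIds)
})

#' Per-sample prediction sets
#'
#' @param x a PredictionSetTable.
#' @return named list of character vectors.
#' @name predictionSets
NULL

#' @rdname predictionSets
#' @export
setMethod("predictionSets", "PredictionSetTable", function(x) {
  structure(x@sets, names = x@sampleIds)
})

#' Size categories of prediction sets
#'
#' @param x a PredictionSetTable.
#' @return character vector: "empty", "certain" or "uncertain".
#' @name sizeCategory
NULL

#' @rdname sizeCategory
#' @export
setMethod("sizeCategory", "PredictionSetTable", function(x) {
  structure(x@sizeCategory, names = x@sampleIds)
})

#' FNR tolerance
#'
#' @param x a CalibratedModel or CrossValResult.
#' @return numeric tolerance alpha.
#' @name alpha
NULL

#' @rdname alpha
#' @export
setMethod("alpha", "CalibratedModel", function(x) x@alpha)
#' @rdname alpha
#' @export
setMethod("alpha", "CrossValResult", function(x) x@alpha)

#' Calibrated score threshold
#'
#' @param x a CalibratedModel.
#' @return numeric threshold lamhat in \[0,1\].
#' @name lamhat
NULL

#' @rdname lamhat
#' @export
setMethod("lamhat", "CalibratedModel", function(x) x@lamhat)

#' Calibration sample count
#'
#' @param x a CalibratedModel or RiskCurve.
#' @return integer count.
#' @name nCal
NULL

#' @rdname nCal
#' @export
setMethod("nCal", "CalibratedModel", function(x) x@nCal)
#' @rdname nCal
#' @export
setMethod("nCal", "RiskCurve", function(x) x@nCal)

#' Per-sample loss bound
#'
#' @param x a CalibratedModel or RiskCurve.
#' @return numeric bound B.
#' @name lossBound
NULL

#' @rdname lossBound
#' @export
setMethod("lossBound", "CalibratedModel", function(x) x@lossBound)
#' @rdname lossBound
#' @export
setMethod("lossBound", "RiskCurve", function(x) x@lossBound)

#' Overall false-negative rate
#'
#' @param x an EvalReport or CrossValResult.
#' @return FNR as a percentage (for CrossValResult, the mean across runs).
#' @name overallFnr
NULL

#' @rdname overallFnr
#' @export
setMethod("overallFnr", "EvalReport", function(x) x@overallFnr)
#' @rdname overallFnr
#' @export
setMethod("overallFnr", "CrossValResult", function(x) x@meanFnr)

#' Mean prediction-set size
#'
#' @param x an EvalReport or CrossValResult.
#' @return numeric mean set size.
#' @name meanSetSize
NULL

#' @rdname meanSetSize
#' @export
setMethod("meanSetSize", "EvalReport", function(x) x@meanSetSize)
#' @rdname meanSetSize
#' @export
setMethod("meanSetSize", "CrossValResult", function(x) x@meanSetSize)

#' Empty / certain / uncertain proportions
#'
#' @param x an EvalReport or CrossValResult.
#' @return named numeric of fractions (empty, certain, uncertain) summing
#'   to 1; for CrossValResult, means across runs.
#' @name sizeProportions
NULL

#' @rdname sizeProportions
#' @export
setMethod("sizeProportions", "EvalReport", function(x) {
  c(empty = x@propEmpty, certain = x@propCertain, uncertain = x@propUncertain)
})
#' @rdname sizeProportions
#' @export
setMethod("sizeProportions", "CrossValResult", function(x) {
  c(empty = mean(x@runPropEmpty), certain = mean(x@runPropCertain),
    uncertain = mean(x@runPropUncertain))
})

#' Per-class stratified summary
#'
#' @param x an EvalReport or CrossValResult.
#' @return data.frame of per-true-class summaries (single-label samples).
#' @name perClass
NULL

#' @rdname perClass
#' @export
setMethod("perClass", "EvalReport", function(x) x@perClass)
#' @rdname perClass
#' @export
setMethod("perClass", "CrossValResult", function(x) x@perClass)

#' Exact set-composition counts
#'
#' @param x an EvalReport.
#' @return data.frame with columns set and count.
#' @name setCompositions
NULL

#' @rdname setCompositions
#' @export
setMethod("setCompositions", "EvalReport", function(x) x@setCompositions)

#' Selected tolerance from an alpha scan
#'
#' @param x an AlphaScan.
#' @return the alpha maximizing the cross-validated certain-set proportion.
#' @name selectedAlpha
NULL

#' @rdname selectedAlpha
#' @export
setMethod("selectedAlpha", "AlphaScan", function(x) x@selectedAlpha)

#' Alpha-scan grid table
#'
#' @param x an AlphaScan.
#' @return the grid data.frame (alpha, lamhat, feasible, proportions, selected).
#' @name alphaGrid
NULL

#' @rdname alphaGrid
#' @export
setMethod("alphaGrid", "AlphaScan", function(x) x@grid)
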