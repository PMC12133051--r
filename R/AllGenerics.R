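#' @rdname sampleIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname classNames
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname scores
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname labelSets
#' @export
setGeneric("labelSets", function(x) standardGeneric("labelSets"))

#' @rdname predictionSets
#' @export
setGeneric("predictionSets", function(x) standardGeneric("predictionSets"))

#' @rdname sizeCategory
#' @export
setGeneric("sizeCategory", function(x) standardGeneric("sizeCategory"))

#' @rdname alpha
#' @export
setGeneric("alpha", function(x) standardGeneric("alpha"))

#' @rdname lamhat
#' @export
setGeneric("lamhat", function(x) standardGeneric("lamhat"))

#' @rdname nCal
#' @export
setGeneric("nCal", function(x) standardGeneric("nCal"))

#' @rdname lossBound
#' @export
setGeneric("lossBound", function(x) standardGeneric("lossBound"))

#' @rdname overallFnr
#' @export
setGeneric("overallFnr", function(x) standardGeneric("overallFnr"))

#' @rdname meanSetSize
#' @export
setGeneric("meanSetSize", function(x) standardGeneric("meanSetSize"))

#' @rdname sizeProportions
#' @export
setGeneric("sizeProportions", function(x) standardGeneric("sizeProportions"))

#' @rdname perClass
#' @export
setGeneric("perClass", function(x) standardGeneric("perClass"))

#' @rdname setCompositions
#' @export
setGeneric("setCompositions", function(x) standardGeneric("setCompositions"))

#' @rdname selectedAlpha
#' @export
setGeneric("selectedAlpha", function(x) standardGeneric("selectedAlpha"))

#' @rdname alphaGrid
#' @export
setGeneric("alphaGrid", function(x) standardGeneric("alphaGrid"))

#' @rdname asTable
#' @export
setGeneric("asTable", function(x, ...) standardGeneric("asTable"))
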