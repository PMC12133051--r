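#' @import methods
NULL

## Condition helpers -------------------------------------------------------

.stopValidation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("setconformValidationError", "setconformError")))
}

.stopConfig <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("setconformConfigError", "setconformError")))
}

.stopInfeasible <- function(msg, minAlpha) {
  stop(errorCondition(msg, minAlpha = minAlpha,
                      class = c("setconformInfeasibleAlphaError", "setconformError")))
}

## ScoreMatrix -------------------------------------------------------------

#' ScoreMatrix: classifier scores for samples across classes
#'
#' An S4 container for an n x K matrix of per-class classifier scores in
#' \[0,1\] (for example, softmax outputs of a molecular subtype classifier).
#' Rows are samples, columns are classes. Rows are *not* required to sum to 1:
#' one-vs-rest style outputs, where two classes may simultaneously score high,
#' are permitted and never renormalized.
#'
#' @slot scores numeric matrix with unique, non-empty rownames (sample
#'   identifiers) and colnames (class names, K >= 2); all entries finite and in
#'   \[0,1\].
#'
#' @seealso [readScores()], [simulateScores()], [formSets()]
#' @export
setClass("ScoreMatrix", representation(scores = "matrix"))

setValidity("ScoreMatrix", function(object) {
  s <- object@scores
  if (!is.numeric(s)) return("scores must be a numeric matrix")
  if (is.null(rownames(s)) || is.null(colnames(s)))
    return("scores must have rownames (sample ids) and colnames (class names)")
  if (ncol(s) < 2) return("at least 2 classes are required")
  if (anyDuplicated(rownames(s))) return("duplicate sample ids")
  if (anyDuplicated(colnames(s))) return("duplicate class names")
  bad <- which(!is.finite(s) | s < 0 | s > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    return(sprintf("score out of [0,1] or non-finite for sample '%s', class '%s': %s",
                   rownames(s)[i], colnames(s)[j], format(s[i, j])))
  }
  TRUE
})

#' Construct a ScoreMatrix
#'
#' @param scores numeric matrix (samples x classes) with rownames and colnames.
#' @return a validated [ScoreMatrix-class] object.
#' @examples
#' m <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("A", "B")))
#' ScoreMatrix(m)
#' @export
ScoreMatrix <- function(scores) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  new("ScoreMatrix", scores = scores)
}

## LabelTable --------------------------------------------------------------

#' LabelTable: true class labels per sample
#'
#' Holds, for each sample, a set of zero or more true class names. An empty
#' set encodes an unknown subtype; samples used for calibration must have at
#' least one label, while unknown samples are still legal inputs for
#' prediction-set accounting.
#'
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot labels list of character vectors, one per sample (possibly empty).
#'
#' @seealso [readLabels()], [calibrate()], [evaluateSets()]
#' @export
setClass("LabelTable",
         representation(sampleIds = "character", labels = "list"))

setValidity("LabelTable", function(object) {
  if (length(object@sampleIds) != length(object@labels))
    return("sampleIds and labels must have equal length")
  if (anyDuplicated(object@sampleIds)) return("duplicate sample ids")
  ok <- vapply(object@labels, function(l)
    is.character(l) && !anyDuplicated(l) && !anyNA(l), logical(1))
  if (!all(ok)) return("each label entry must be a character vector without NA or duplicates")
  TRUE
})

#' Construct a LabelTable
#'
#' @param sampleIds character vector of sample identifiers.
#' @param labels list of character vectors (one per sample; empty = unknown),
#'   or a character vector of single labels.
#' @return a validated [LabelTable-class] object.
#' @examples
#' LabelTable(c("S1", "S2"), list("A", c("A", "B")))
#' @export
LabelTable <- function(sampleIds, labels) {
  if (is.character(labels)) labels <- as.list(labels)
  labels <- lapply(labels, function(l) if (length(l) == 0) character(0) else as.character(l))
  names(labels) <- NULL
  new("LabelTable", sampleIds = as.character(sampleIds), labels = labels)
}

## PredictionSetTable ------------------------------------------------------

#' PredictionSetTable: per-sample prediction sets
#'
#' The output of prediction-set formation: for each sample, the set of class
#' names whose score passed the rule, together with its size category:
#' \code{empty} (size 0, the model does not recognize the input),
#' \code{certain} (size 1, a confident single-class call) or
#' \code{uncertain} (size >= 2, ambiguity between classes).
#'
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot sets list of character vectors of class names.
#' @slot sizeCategory character vector; one of "empty", "certain", "uncertain",
#'   consistent with the set sizes.
#'
#' @seealso [formSets()], [top1Sets()], [fixedThresholdSets()]
#' @export
setClass("PredictionSetTable",
         representation(sampleIds = "character", sets = "list",
                        sizeCategory = "character"))

setValidity("PredictionSetTable", function(object) {
  n <- length(object@sampleIds)
  if (length(object@sets) != n || length(object@sizeCategory) != n)
    return("sampleIds, sets and sizeCategory must have equal length")
  if (anyDuplicated(object@sampleIds)) return("duplicate sample ids")
  sz <- lengths(object@sets)
  want <- ifelse(sz == 0, "empty", ifelse(sz == 1, "certain", "uncertain"))
  if (!identical(unname(object@sizeCategory), unname(want)))
    return("sizeCategory inconsistent with set sizes")
  TRUE
})

#' Construct a PredictionSetTable
#'
#' The size category is derived from the set sizes.
#'
#' @param sampleIds character vector of sample identifiers.
#' @param sets list of character vectors of predicted class names.
#' @return a validated [PredictionSetTable-class] object.
#' @export
PredictionSetTable <- function(sampleIds, sets) {
  sets <- lapply(sets, as.character)
  names(sets) <- NULL
  sz <- lengths(sets)
  cat_ <- ifelse(sz == 0, "empty", ifelse(sz == 1, "certain", "uncertain"))
  new("PredictionSetTable", sampleIds = as.character(sampleIds),
      sets = sets, sizeCategory = cat_)
}

## CalibratedModel ---------------------------------------------------------

#' CalibratedModel: a calibrated FNR-controlling threshold
#'
#' Stores the result of conformal risk control calibration: the FNR tolerance
#' alpha, the calibrated score threshold lamhat (classes scoring at or above
#' it enter the prediction set), the calibration sample count, the per-sample
#' loss bound B (1 for the fractional FNR loss), and the class universe.
#'
#' The feasibility invariant alpha >= B/(n_cal + 1) is enforced: below that
#' bound the conformal guarantee cannot be certified for any threshold.
#'
#' @slot alpha numeric; target FNR tolerance in (0,1).
#' @slot lamhat numeric; calibrated score threshold in \[0,1\].
#' @slot nCal integer; number of calibration samples.
#' @slot lossBound numeric; maximum per-sample loss B (default 1).
#' @slot classNames character; class universe the model applies to.
#' @slot inclusionRule character; fixed to "score >= lamhat".
#'
#' @seealso [calibrate()], [formSets()], [writeModel()]
#' @export
setClass("CalibratedModel",
         representation(alpha = "numeric", lamhat = "numeric",
                        nCal = "integer", lossBound = "numeric",
                        classNames = "character", inclusionRule = "character"))

setValidity("CalibratedModel", function(object) {
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    return("alpha must be a single value in (0,1)")
  if (length(object@lamhat) != 1 || object@lamhat < 0 || object@lamhat > 1)
    return("lamhat must lie within [0,1]")
  if (length(object@nCal) != 1 || object@nCal < 1)
    return("nCal must be a positive integer")
  if (length(object@lossBound) != 1 || object@lossBound <= 0)
    return("lossBound must be positive")
  if (object@alpha < object@lossBound / (object@nCal + 1) - 1e-12)
    return(sprintf("alpha (%g) below the feasibility bound B/(n_cal+1) = %g",
                   object@alpha, object@lossBound / (object@nCal + 1)))
  if (length(object@classNames) < 2 || anyDuplicated(object@classNames))
    return("classNames must be >= 2 unique names")
  if (!identical(object@inclusionRule, "score >= lamhat"))
    return("inclusionRule must be 'score >= lamhat'")
  TRUE
})

#' Construct a CalibratedModel
#'
#' Usually produced by [calibrate()]; the constructor is exported for
#' round-tripping persisted models.
#'
#' @param alpha FNR tolerance in (0,1).
#' @param lamhat score threshold in \[0,1\].
#' @param nCal calibration sample count.
#' @param classNames class universe.
#' @param lossBound per-sample loss bound B (default 1).
#' @return a validated [CalibratedModel-class] object.
#' @export
CalibratedModel <- function(alpha, lamhat, nCal, classNames, lossBound = 1) {
  new("CalibratedModel", alpha = as.numeric(alpha), lamhat = as.numeric(lamhat),
      nCal = as.integer(nCal), lossBound = as.numeric(lossBound),
      classNames = as.character(classNames), inclusionRule = "score >= lamhat")
}

## RiskCurve ---------------------------------------------------------------

#' RiskCurve: empirical and adjusted FNR risk along candidate thresholds
#'
#' The constraint-function output of calibration: for each candidate threshold
#' t, the empirical mean FNR loss on the calibration data, R-hat(t), and the
#' conformal adjusted risk (n/(n+1)) * R-hat(t) + B/(n+1). The calibrated
#' lamhat is the largest threshold whose adjusted risk stays at or below the
#' tolerance alpha.
#'
#' @slot thresholds ascending numeric candidate thresholds in \[0,1\].
#' @slot empiricalRisk numeric; R-hat at each threshold (nondecreasing).
#' @slot adjustedRisk numeric; adjusted risk at each threshold.
#' @slot nCal integer; calibration sample count.
#' @slot lossBound numeric; loss bound B.
#'
#' @seealso [riskCurve()], [calibrate()]
#' @export
setClass("RiskCurve",
         representation(thresholds = "numeric", empiricalRisk = "numeric",
                        adjustedRisk = "numeric", nCal = "integer",
                        lossBound = "numeric"))

setValidity("RiskCurve", function(object) {
  k <- length(object@thresholds)
  if (length(object@empiricalRisk) != k || length(object@adjustedRisk) != k)
    return("thresholds, empiricalRisk and adjustedRisk must align")
  if (is.unsorted(object@thresholds, strictly = TRUE))
    return("thresholds must be strictly ascending")
  if (is.unsorted(object@empiricalRisk))
    return("empiricalRisk must be nondecreasing in threshold")
  n <- object@nCal; B <- object@lossBound
  resid <- object@adjustedRisk - object@empiricalRisk * n / (n + 1)
  if (any(abs(resid - B / (n + 1)) > 1e-9))
    return("adjustedRisk must equal (n/(n+1)) * empiricalRisk + B/(n+1)")
  TRUE
})

## EvalReport --------------------------------------------------------------

#' EvalReport: evaluation of prediction sets against true labels
#'
#' Summarizes a [PredictionSetTable-class] against a [LabelTable-class]:
#' overall FNR (percent, labeled samples only), mean set size, the
#' empty/certain/uncertain proportions over all evaluated samples, per-class
#' strata for single-label samples, exact set-composition counts, and the
#' fraction of multiclass sets containing each class.
#'
#' @slot overallFnr numeric; percent in \[0,100\] (NA when no labeled sample).
#' @slot meanSetSize numeric; mean prediction-set size over all samples.
#' @slot propEmpty,propCertain,propUncertain numeric fractions summing to 1.
#' @slot perClass data.frame with columns class, n, fnr (percent),
#'   meanSetSize, meanFalsePositiveScore (NA without a score matrix).
#' @slot setCompositions data.frame with columns set (";"-joined members,
#'   "" for the empty set) and count; counts sum to the sample count.
#' @slot cooccurrence named numeric; per class, the fraction of multiclass
#'   (size >= 2) sets containing it (NA when there are none).
#' @slot multiTruthFnr numeric; percent FNR over multi-label-truth samples
#'   (NA when there are none).
#' @slot nSamples,nLabeled,nMultiTruth integer accounting.
#' @slot lossType character; "fractional" or "allOrNothing".
#'
#' @seealso [evaluateSets()]
#' @export
setClass("EvalReport",
         representation(overallFnr = "numeric", meanSetSize = "numeric",
                        propEmpty = "numeric", propCertain = "numeric",
                        propUncertain = "numeric", perClass = "data.frame",
                        setCompositions = "data.frame",
                        cooccurrence = "numeric", multiTruthFnr = "numeric",
                        nSamples = "integer", nLabeled = "integer",
                        nMultiTruth = "integer", lossType = "character"))

setValidity("EvalReport", function(object) {
  p <- object@propEmpty + object@propCertain + object@propUncertain
  if (object@nSamples > 0 && abs(p - 1) > 1e-12)
    return("size-category proportions must sum to 1")
  if (!is.na(object@overallFnr) &&
      (object@overallFnr < 0 || object@overallFnr > 100))
    return("overallFnr must lie in [0,100]")
  if (nrow(object@perClass) > 0 &&
      any(object@perClass$fnr < -1e-9 | object@perClass$fnr > 100 + 1e-9))
    return("per-class FNRs must lie in [0,100]")
  if (sum(object@setCompositions$count) != object@nSamples)
    return("set-composition counts must sum to the sample count")
  TRUE
})

## CrossValResult ----------------------------------------------------------

#' CrossValResult: repeated shuffle-split cross-validation of the guarantee
#'
#' Per-run held-out FNR and mean set size across independent
#' calibration/validation shuffle splits, with aggregate means and Monte-Carlo
#' standard errors (sd across runs / sqrt(n_runs)), plus per-class aggregates
#' pooled over runs.
#'
#' @slot alpha numeric; FNR tolerance used in every run.
#' @slot nRuns integer; number of shuffle-split runs.
#' @slot calFraction numeric; fraction of labeled samples used for calibration.
#' @slot seed integer; seed the splits were derived from.
#' @slot runFnr numeric length nRuns; held-out FNR percent per run.
#' @slot runSetSize numeric length nRuns; held-out mean set size per run.
#' @slot runPropEmpty,runPropCertain,runPropUncertain numeric length nRuns.
#' @slot meanFnr,seFnr,meanSetSize,seSetSize numeric aggregates.
#' @slot perClass data.frame with columns class, n (pooled single-label test
#'   occurrences), fnr (percent), meanSetSize.
#'
#' @seealso [crossValidate()]
#' @export
setClass("CrossValResult",
         representation(alpha = "numeric", nRuns = "integer",
                        calFraction = "numeric", seed = "integer",
                        runFnr = "numeric", runSetSize = "numeric",
                        runPropEmpty = "numeric", runPropCertain = "numeric",
                        runPropUncertain = "numeric",
                        meanFnr = "numeric", seFnr = "numeric",
                        meanSetSize = "numeric", seSetSize = "numeric",
                        perClass = "data.frame"))

setValidity("CrossValResult", function(object) {
  n <- object@nRuns
  lens <- c(length(object@runFnr), length(object@runSetSize),
            length(object@runPropEmpty), length(object@runPropCertain),
            length(object@runPropUncertain))
  if (any(lens != n)) return("per-run vectors must have length nRuns")
  if (abs(object@meanFnr - mean(object@runFnr)) > 1e-9)
    return("meanFnr must equal the mean of per-run FNRs")
  if (abs(object@meanSetSize - mean(object@runSetSize)) > 1e-9)
    return("meanSetSize must equal the mean of per-run set sizes")
  TRUE
})

## AlphaScan ---------------------------------------------------------------

#' AlphaScan: empirical error-rate selection over a tolerance grid
#'
#' For each tolerance alpha on an ascending grid: the whole-data calibrated
#' lamhat, and the cross-validated mean proportions of empty / certain /
#' uncertain prediction sets. The selected alpha maximizes the mean certain
#' (single-class) proportion, ties broken toward the smallest alpha (the
#' stronger guarantee at equal certainty).
#'
#' @slot grid data.frame with columns alpha, lamhat, feasible, propEmpty,
#'   propCertain, propUncertain, selected.
#' @slot selectedAlpha numeric; a member of the grid.
#' @slot nRuns integer; cross-validation runs per grid point.
#' @slot calFraction numeric.
#' @slot seed integer.
#'
#' @seealso [selectAlpha()], [lamhatCurve()]
#' @export
setClass("AlphaScan",
         representation(grid = "data.frame", selectedAlpha = "numeric",
                        nRuns = "integer", calFraction = "numeric",
                        seed = "integer"))

setValidity("AlphaScan", function(object) {
  g <- object@grid
  need <- c("alpha", "lamhat", "feasible", "propEmpty", "propCertain",
            "propUncertain", "selected")
  if (!all(need %in% names(g))) return("grid is missing required columns")
  if (is.unsorted(g$alpha, strictly = TRUE))
    return("alpha grid must be strictly ascending")
  lh <- g$lamhat[g$feasible]
  if (length(lh) > 1 && is.unsorted(lh + 1e-12))
    return("lamhat must be nondecreasing along the feasible grid")
  ps <- g[g$feasible, c("propEmpty", "propCertain", "propUncertain")]
  if (nrow(ps) > 0 && any(abs(rowSums(ps) - 1) > 1e-9))
    return("per-alpha proportions must sum to 1")
  if (!object@selectedAlpha %in% g$alpha)
    return("selectedAlpha must be a member of the grid")
  TRUE
})

## SimulationSpec ----------------------------------------------------------

#' SimulationSpec: parameters of the synthetic classifier-score generator
#'
#' Describes a population of classifier outputs with known truth: imbalanced
#' class frequencies, scaled-beta score distributions for on-target,
#' confusable and background classes, a confusion-weight matrix giving each
#' true class a propensity to elevate specific off-target classes, a fraction
#' of samples carrying two true labels, and a fraction of out-of-distribution
#' samples whose scores are all background draws and whose truth is empty.
#'
#' @slot classNames character; K >= 2 unique class labels.
#' @slot classFrequencies numeric probability vector of length K (sums to 1).
#' @slot confusionWeights K x K nonnegative matrix in \[0,1\]; row = true
#'   class; entry (j,k) = probability that class k draws an elevated
#'   (confused) score when the true class is j; the diagonal is ignored.
#' @slot onTargetShape,offTargetShape,confusedShape numeric length-2 positive
#'   beta shape parameters for true-class, background, and confusable-class
#'   scores respectively.
#' @slot multiTruthFraction numeric; fraction of samples with 2 true labels.
#' @slot oodFraction numeric; fraction of out-of-distribution samples.
#' @slot nSamples integer; rows to generate.
#' @slot seed integer; drives one explicit random stream; identical seed gives
#'   identical output.
#'
#' @seealso [simulateScores()], [presetAlliumLike()]
#' @export
setClass("SimulationSpec",
         representation(classNames = "character", classFrequencies = "numeric",
                        confusionWeights = "matrix", onTargetShape = "numeric",
                        offTargetShape = "numeric", confusedShape = "numeric",
                        multiTruthFraction = "numeric", oodFraction = "numeric",
                        nSamples = "integer", seed = "integer"))

setValidity("SimulationSpec", function(object) {
  K <- length(object@classNames)
  if (K < 2 || anyDuplicated(object@classNames))
    return("classNames must be >= 2 unique labels")
  if (length(object@classFrequencies) != K)
    return("classFrequencies must have one entry per class")
  if (any(object@classFrequencies < 0) ||
      abs(sum(object@classFrequencies) - 1) > 1e-9)
    return("classFrequencies must be nonnegative and sum to 1")
  w <- object@confusionWeights
  if (!all(dim(w) == c(K, K))) return("confusionWeights must be K x K")
  if (any(w < 0 | w > 1)) return("confusionWeights must lie in [0,1]")
  if (any(diag(w) != 0)) return("confusionWeights diagonal must be zero")
  for (nm in c("onTargetShape", "offTargetShape", "confusedShape")) {
    sh <- slot(object, nm)
    if (length(sh) != 2 || any(sh <= 0))
      return(sprintf("%s must be two positive shape parameters", nm))
  }
  if (object@multiTruthFraction < 0 || object@oodFraction < 0 ||
      object@multiTruthFraction + object@oodFraction > 1)
    return("multiTruthFraction + oodFraction must lie in [0,1]")
  if (object@nSamples < 1) return("nSamples must be >= 1")
  TRUE
})
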