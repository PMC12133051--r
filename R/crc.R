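## Conformal risk control engine.
##
## Calibration selects the largest score threshold lamhat whose conformally
## adjusted empirical FNR risk, (n/(n+1)) * R-hat(t) + B/(n+1), stays at or
## below the tolerance alpha. R-hat is a step function that changes only at
## scores assigned to true labels, so scanning the candidate set
## {0} union {unique true-label scores} finds the exact supremum without a
## grid. Classes enter a prediction set when their score is >= lamhat (closed
## rule, so risk changes exactly at the candidate values).

## Align a ScoreMatrix and LabelTable on their common samples.
.joinScoresLabels <- function(scoreMatrix, labelTable) {
  m <- scores(scoreMatrix)
  ids <- intersect(rownames(m), sampleIds(labelTable))
  if (length(ids) == 0)
    .stopValidation("no samples in common between scores and labels")
  labs <- labelSets(labelTable)[ids]
  unknownClasses <- setdiff(unique(unlist(labs)), colnames(m))
  if (length(unknownClasses) > 0)
    .stopValidation("label(s) absent from score-matrix classes: %s",
                    paste(unknownClasses, collapse = ", "))
  list(mat = m[ids, , drop = FALSE], labels = labs)
}

## True-label scores with per-sample fractional weights 1/|truth|;
## labeled samples only.
.trueScoreWeights <- function(mat, labs) {
  keep <- lengths(labs) > 0
  if (!any(keep))
    .stopValidation("no labeled samples available")
  mat <- mat[keep, , drop = FALSE]
  labs <- labs[keep]
  n <- nrow(mat)
  cls <- colnames(mat)
  idx <- rep.int(seq_len(n), lengths(labs))
  col <- match(unlist(labs, use.names = FALSE), cls)
  ts <- mat[cbind(idx, col)]
  w <- 1 / lengths(labs)[idx]
  list(ts = ts, w = w, n = n)
}

## Exact empirical/adjusted risk at the candidate thresholds.
## R-hat(t) = (1/n) * sum of weights of true-label scores strictly below t.
.riskAtCandidates <- function(ts, w, n, lossBound) {
  o <- order(ts)
  tss <- ts[o]; ws <- w[o]
  last <- which(c(diff(tss) > 0, TRUE))
  su <- tss[last]
  cumBelowOrAt <- cumsum(ws)[last]
  riskAt <- c(0, cumBelowOrAt[-length(su)]) / n   # weight strictly below su_j
  if (su[1] > 0) {
    cand <- c(0, su)
    risk <- c(0, riskAt)
  } else {
    cand <- su
    risk <- riskAt
  }
  adjusted <- risk * n / (n + 1) + lossBound / (n + 1)
  list(thresholds = cand, empiricalRisk = risk, adjustedRisk = adjusted)
}

## Fast path shared by calibrate() and the cross-validation loop.
.calibrateLamhat <- function(ts, w, n, alpha, lossBound) {
  minAlpha <- lossBound / (n + 1)
  if (alpha < minAlpha - 1e-12)
    .stopInfeasible(sprintf(
      "alpha = %g is infeasible for n_cal = %d: the minimum achievable tolerance is B/(n+1) = %g",
      alpha, n, minAlpha), minAlpha)
  rc <- .riskAtCandidates(ts, w, n, lossBound)
  feasible <- rc$adjustedRisk <= alpha + 1e-12
  rc$thresholds[max(which(feasible))]
}

#' Per-sample false-negative-rate loss
#'
#' The fraction of a sample's true class labels missing from its prediction
#' set: |truth \\ set| / |truth|. For single-label truth this is the 0/1 miss
#' indicator; for multi-label truth it is fractional and bounded by 1, the
#' monotone loss that conformal risk control requires.
#'
#' @param predictionSet character vector of predicted classes (may be empty).
#' @param trueLabels nonempty character vector of true classes.
#' @return a fraction in \[0,1\].
#' @examples
#' fnrLoss(c("A", "B"), "A")      # 0
#' fnrLoss(character(0), "A")     # 1
#' fnrLoss("A", c("A", "B"))      # 0.5
#' @export
fnrLoss <- function(predictionSet, trueLabels) {
  if (length(trueLabels) == 0)
    .stopValidation("trueLabels must be nonempty: unknown-subtype samples are never scored for loss")
  sum(!(trueLabels %in% predictionSet)) / length(trueLabels)
}

#' Empirical FNR at a fixed score threshold
#'
#' Mean [fnrLoss()] over labeled samples when prediction sets are formed by
#' including every class scoring at or above `threshold`. Unlabeled (unknown)
#' samples are excluded; it is an error if none remain.
#'
#' @param threshold score threshold in \[0,1\].
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param labelTable a [LabelTable-class].
#' @return mean FNR loss, a fraction in \[0,1\].
#' @export
empiricalFnr <- function(threshold, scoreMatrix, labelTable) {
  stopifnot(threshold >= 0, threshold <= 1)
  j <- .joinScoresLabels(scoreMatrix, labelTable)
  tw <- .trueScoreWeights(j$mat, j$labels)
  sum(tw$w[tw$ts < threshold]) / tw$n
}

#' Empirical and adjusted risk along candidate thresholds
#'
#' Computes the constraint function of conformal risk control on labeled
#' calibration data: for every candidate threshold (0 plus each unique score
#' assigned to a true label) the empirical mean FNR loss R-hat(t) and the
#' adjusted risk (n/(n+1)) * R-hat(t) + B/(n+1). Both are nondecreasing in t.
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param labelTable a [LabelTable-class]; unlabeled samples are excluded.
#' @param lossBound per-sample loss bound B (default 1).
#' @return a [RiskCurve-class]; export with [asTable()].
#' @export
riskCurve <- function(scoreMatrix, labelTable, lossBound = 1) {
  j <- .joinScoresLabels(scoreMatrix, labelTable)
  tw <- .trueScoreWeights(j$mat, j$labels)
  rc <- .riskAtCandidates(tw$ts, tw$w, tw$n, lossBound)
  new("RiskCurve", thresholds = rc$thresholds,
      empiricalRisk = rc$empiricalRisk, adjustedRisk = rc$adjustedRisk,
      nCal = as.integer(tw$n), lossBound = as.numeric(lossBound))
}

#' Calibrate an FNR-controlling score threshold
#'
#' Split conformal risk control: given calibration scores and true labels and
#' a tolerance alpha, selects
#' lamhat = max\{ t : (n/(n+1)) * R-hat(t) + B/(n+1) <= alpha \}
#' over the candidate thresholds \{0\} union \{unique true-label scores\}.
#' Prediction sets formed on exchangeable future samples by including every
#' class scoring >= lamhat then have expected FNR at most alpha.
#'
#' Tolerances below B/(n+1) are infeasible (even the all-classes set cannot
#' certify them) and raise an error reporting the minimum achievable alpha;
#' see [minFeasibleAlpha()].
#'
#' @param scoreMatrix a [ScoreMatrix-class] of calibration scores.
#' @param labelTable a [LabelTable-class]; unlabeled samples are excluded
#'   (calibration requires at least one true label per sample).
#' @param alpha FNR tolerance in (0,1).
#' @param lossBound per-sample loss bound B (default 1).
#' @return a [CalibratedModel-class].
#' @examples
#' m <- matrix(c(0.9, 0.8, 0.7, 0.6, 0.1, 0.2, 0.1, 0.3), 4, 2,
#'             dimnames = list(paste0("S", 1:4), c("A", "B")))
#' sm <- ScoreMatrix(m)
#' lt <- LabelTable(paste0("S", 1:4), rep("A", 4))
#' lamhat(calibrate(sm, lt, alpha = 0.2))   # 0.6
#' @export
calibrate <- function(scoreMatrix, labelTable, alpha, lossBound = 1) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  j <- .joinScoresLabels(scoreMatrix, labelTable)
  tw <- .trueScoreWeights(j$mat, j$labels)
  lh <- .calibrateLamhat(tw$ts, tw$w, tw$n, alpha, lossBound)
  CalibratedModel(alpha = alpha, lamhat = lh, nCal = tw$n,
                  classNames = classNames(scoreMatrix), lossBound = lossBound)
}

#' Form prediction sets from a calibrated model
#'
#' For every sample, the set of model classes whose score is at or above the
#' calibrated lamhat. Empty sets are legal outputs and signal that the model
#' does not recognize the input.
#'
#' @param scoreMatrix a [ScoreMatrix-class]; must contain every model class.
#' @param model a [CalibratedModel-class].
#' @return a [PredictionSetTable-class].
#' @export
formSets <- function(scoreMatrix, model) {
  stopifnot(is(model, "CalibratedModel"))
  miss <- setdiff(model@classNames, classNames(scoreMatrix))
  if (length(miss) > 0)
    .stopValidation("score matrix is missing model class(es): %s",
                    paste(miss, collapse = ", "))
  m <- scores(scoreMatrix)[, model@classNames, drop = FALSE]
  inc <- m >= model@lamhat
  sets <- lapply(seq_len(nrow(m)), function(i) model@classNames[inc[i, ]])
  PredictionSetTable(rownames(m), sets)
}

#' Minimum feasible FNR tolerance
#'
#' The smallest tolerance the conformal risk control guarantee can certify
#' with n calibration samples and per-sample loss bound B: B/(n+1).
#'
#' @param nCal calibration sample count (>= 1).
#' @param lossBound per-sample loss bound B (default 1).
#' @return the bound B/(nCal + 1).
#' @examples
#' minFeasibleAlpha(4)     # 0.2
#' minFeasibleAlpha(999)   # 0.001
#' @export
minFeasibleAlpha <- function(nCal, lossBound = 1) {
  stopifnot(nCal >= 1)
  lossBound / (nCal + 1)
}
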