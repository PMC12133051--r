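setMethod("show", "ScoreMatrix", function(object) {
  cat(sprintf("ScoreMatrix: %d samples x %d classes\n",
              nrow(object@scores), ncol(object@scores)))
  cat("  classes:", paste(utils::head(colnames(object@scores), 6), collapse = ", "),
      if (ncol(object@scores) > 6) "..." else "", "\n")
  cat(sprintf("  score range: [%.3f, %.3f]\n",
              min(object@scores), max(object@scores)))
})

setMethod("show", "LabelTable", function(object) {
  sz <- lengths(object@labels)
  cat(sprintf("LabelTable: %d samples (%d single-label, %d multi-label, %d unknown)\n",
              length(sz), sum(sz == 1), sum(sz > 1), sum(sz == 0)))
})

setMethod("show", "PredictionSetTable", function(object) {
  tab <- table(factor(object@sizeCategory,
                      levels = c("empty", "certain", "uncertain")))
  cat(sprintf("PredictionSetTable: %d samples\n", length(object@sampleIds)))
  cat(sprintf("  empty: %d  certain: %d  uncertain: %d  mean size: %.2f\n",
              tab["empty"], tab["certain"], tab["uncertain"],
              mean(lengths(object@sets))))
})

setMethod("show", "CalibratedModel", function(object) {
  cat("CalibratedModel (conformal risk control, FNR loss)\n")
  cat(sprintf("  alpha (FNR tolerance): %g\n", object@alpha))
  cat(sprintf("  lamhat (threshold):    %.6g  [reported rounded: %.2f]\n",
              object@lamhat, round(object@lamhat, 2)))
  cat(sprintf("  calibration n: %d   loss bound B: %g   rule: %s\n",
              object@nCal, object@lossBound, object@inclusionRule))
  cat(sprintf("  classes: %d\n", length(object@classNames)))
})

setMethod("show", "RiskCurve", function(object) {
  cat(sprintf("RiskCurve: %d candidate thresholds (n = %d, B = %g)\n",
              length(object@thresholds), object@nCal, object@lossBound))
  cat(sprintf("  adjusted risk range: [%.4f, %.4f]\n",
              min(object@adjustedRisk), max(object@adjustedRisk)))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  if (is.na(object@overallFnr)) {
    cat("  overall FNR: NA (no labeled samples)\n")
  } else {
    cat(sprintf("  overall FNR: %.2f%% (over %d labeled samples)\n",
                object@overallFnr, object@nLabeled))
  }
  cat(sprintf("  mean set size: %.2f over %d samples\n",
              object@meanSetSize, object@nSamples))
  cat(sprintf("  empty: %.1f%%  certain: %.1f%%  uncertain: %.1f%%\n",
              100 * object@propEmpty, 100 * object@propCertain,
              100 * object@propUncertain))
  if (!is.na(object@multiTruthFnr))
    cat(sprintf("  multi-truth FNR: %.2f%% (n = %d, %s loss)\n",
                object@multiTruthFnr, object@nMultiTruth, object@lossType))
})

setMethod("show", "CrossValResult", function(object) {
  cat(sprintf("CrossValResult: %d runs, alpha = %g, cal fraction = %g\n",
              object@nRuns, object@alpha, object@calFraction))
  cat(sprintf("  mean held-out FNR: %.2f%% (MC se %.3f)\n",
              object@meanFnr, object@seFnr))
  cat(sprintf("  mean set size: %.2f (MC se %.3f)\n",
              object@meanSetSize, object@seSetSize))
})

setMethod("show", "AlphaScan", function(object) {
  cat(sprintf("AlphaScan: %d grid points, %d runs each\n",
              nrow(object@grid), object@nRuns))
  sel <- object@grid[object@grid$selected, , drop = FALSE]
  cat(sprintf("  selected alpha = %g (certain proportion %.1f%%)\n",
              object@selectedAlpha, 100 * sel$propCertain[1]))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf("SimulationSpec: %d samples, %d classes, seed %d\n",
              object@nSamples, length(object@classNames), object@seed))
  cat(sprintf("  multi-truth %.1f%%, OOD %.1f%%, %d confusable pairs\n",
              100 * object@multiTruthFraction, 100 * object@oodFraction,
              sum(object@confusionWeights > 0)))
})
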