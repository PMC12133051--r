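## Empirical error-rate selection: scan a tolerance grid, characterize the
## resulting set-size profile under cross-validation, and pick the tolerance
## maximizing the proportion of certain (single-class) prediction sets.

#' Default tolerance grid
#'
#' 0.05 to 0.50 in steps of 0.025 — covers the customary working range of
#' FNR tolerances (including 0.075, 0.1, 0.15, 0.2, 0.3).
#'
#' @return ascending numeric vector.
#' @export
defaultAlphaGrid <- function() seq(0.05, 0.50, by = 0.025)

#' Calibrated threshold as a function of the tolerance
#'
#' Calibrates once per grid tolerance on the full labeled data and returns
#' the monotone lamhat curve. Infeasible tolerances (below B/(n+1)) are
#' flagged, not silently dropped.
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param labelTable a [LabelTable-class].
#' @param alphaGrid ascending tolerances (default [defaultAlphaGrid()]).
#' @param lossBound per-sample loss bound B (default 1).
#' @return data.frame with columns alpha, lamhat (NA when infeasible),
#'   feasible.
#' @export
lamhatCurve <- function(scoreMatrix, labelTable, alphaGrid = defaultAlphaGrid(),
                        lossBound = 1) {
  stopifnot(!is.unsorted(alphaGrid, strictly = TRUE))
  j <- .joinScoresLabels(scoreMatrix, labelTable)
  tw <- .trueScoreWeights(j$mat, j$labels)
  out <- data.frame(alpha = alphaGrid, lamhat = NA_real_, feasible = FALSE)
  for (i in seq_along(alphaGrid)) {
    lh <- tryCatch(.calibrateLamhat(tw$ts, tw$w, tw$n, alphaGrid[i], lossBound),
                   setconformInfeasibleAlphaError = function(e) NA_real_)
    out$lamhat[i] <- lh
    out$feasible[i] <- !is.na(lh)
  }
  out
}

#' Select the tolerance maximizing certain prediction sets
#'
#' Runs the shuffle-split cross-validation harness once per grid tolerance
#' (identical splits throughout, so tolerances are compared on the same
#' partitions), records the mean proportions of empty / certain / uncertain
#' held-out prediction sets, and selects the tolerance with the highest mean
#' certain proportion. Ties break toward the smallest tolerance — the
#' stronger guarantee at equal certainty. Infeasible grid entries are
#' flagged and excluded from selection.
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param labelTable a [LabelTable-class].
#' @param alphaGrid ascending tolerances (default [defaultAlphaGrid()]).
#' @param nRuns cross-validation runs per tolerance.
#' @param calFraction calibration fraction (default 0.9).
#' @param seed integer seed.
#' @param lossBound per-sample loss bound B (default 1).
#' @return an [AlphaScan-class].
#' @export
selectAlpha <- function(scoreMatrix, labelTable, alphaGrid = defaultAlphaGrid(),
                        nRuns = 100, calFraction = 0.9, seed = 1,
                        lossBound = 1) {
  stopifnot(!is.unsorted(alphaGrid, strictly = TRUE), nRuns >= 1)
  prep <- .cvPrep(scoreMatrix, labelTable)
  nCal <- floor(calFraction * prep$n)
  if (nCal < 1 || nCal >= prep$n)
    .stopValidation("calFraction = %g leaves an empty partition for n = %d",
                    calFraction, prep$n)
  splits <- .makeSplits(prep$n, nRuns, seed)
  lhCurve <- lamhatCurve(scoreMatrix, labelTable, alphaGrid, lossBound)
  grid <- data.frame(alpha = alphaGrid, lamhat = lhCurve$lamhat,
                     feasible = lhCurve$feasible,
                     propEmpty = NA_real_, propCertain = NA_real_,
                     propUncertain = NA_real_, selected = FALSE)
  for (i in seq_along(alphaGrid)) {
    if (!grid$feasible[i] || alphaGrid[i] < lossBound / (nCal + 1) - 1e-12) {
      grid$feasible[i] <- FALSE
      next
    }
    res <- .cvRunsConformal(prep, splits, nCal, alphaGrid[i], lossBound)
    grid$propEmpty[i] <- mean(res$pE)
    grid$propCertain[i] <- mean(res$pC)
    grid$propUncertain[i] <- mean(res$pU)
  }
  if (!any(grid$feasible))
    .stopInfeasible("no grid tolerance is feasible for the calibration size",
                    lossBound / (nCal + 1))
  cand <- which(grid$feasible)
  best <- cand[which.max(grid$propCertain[cand])]  # which.max: earliest max
  grid$selected[best] <- TRUE
  new("AlphaScan", grid = grid, selectedAlpha = alphaGrid[best],
      nRuns = as.integer(nRuns), calFraction = calFraction,
      seed = as.integer(seed))
}
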