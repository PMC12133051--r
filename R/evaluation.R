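## Metrics, uncalibrated baselines, and the repeated shuffle-split
## cross-validation harness that verifies the conformal FNR guarantee.

#' Uncalibrated top-1 prediction sets
#'
#' The baseline a point classifier provides: for each sample, a singleton set
#' holding the top-scoring class when that score reaches the floor, and the
#' empty set otherwise (the classifier declines to predict). Argmax ties are
#' broken toward the earlier class in the column order.
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param floor minimum score for the top class to be emitted (default 0.5,
#'   the customary softmax cutoff of the upstream classifiers).
#' @return a [PredictionSetTable-class] of sets of size 0 or 1.
#' @export
top1Sets <- function(scoreMatrix, floor = 0.5) {
  m <- scores(scoreMatrix)
  best <- max.col(m, ties.method = "first")
  bestVal <- m[cbind(seq_len(nrow(m)), best)]
  cls <- colnames(m)
  sets <- lapply(seq_len(nrow(m)), function(i)
    if (bestVal[i] >= floor) cls[best[i]] else character(0))
  PredictionSetTable(rownames(m), sets)
}

#' Fixed-threshold prediction sets
#'
#' Includes every class whose score passes a fixed threshold — either
#' strictly (score > t, e.g. the "score > 1 - alpha" comparator) or closed
#' (score >= t, e.g. the customary 0.5 cutoff).
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param threshold value in \[0,1\].
#' @param strict logical; if TRUE use score > threshold, else score >= threshold.
#' @return a [PredictionSetTable-class].
#' @export
fixedThresholdSets <- function(scoreMatrix, threshold, strict = FALSE) {
  stopifnot(threshold >= 0, threshold <= 1)
  m <- scores(scoreMatrix)
  inc <- if (strict) m > threshold else m >= threshold
  cls <- colnames(m)
  sets <- lapply(seq_len(nrow(m)), function(i) cls[inc[i, ]])
  PredictionSetTable(rownames(m), sets)
}

#' Evaluate prediction sets against true labels
#'
#' Computes the overall FNR (percent, over labeled samples), the mean set
#' size and empty/certain/uncertain proportions (over all evaluated samples —
#' unknown-subtype samples count here but never toward the FNR), per-class
#' strata for single-label samples, exact set-composition counts, per-class
#' co-occurrence fractions among multiclass sets, and a separate FNR for
#' multi-label-truth samples.
#'
#' @param predictionSetTable a [PredictionSetTable-class].
#' @param labelTable a [LabelTable-class].
#' @param scoreMatrix optional [ScoreMatrix-class]; when supplied, the mean
#'   score of false-positive set members is reported per class.
#' @param lossType "fractional" (default; fraction of true labels missed) or
#'   "allOrNothing" (loss 1 unless every true label is covered). The two
#'   coincide for single-label truth.
#' @return an [EvalReport-class].
#' @export
evaluateSets <- function(predictionSetTable, labelTable, scoreMatrix = NULL,
                         lossType = c("fractional", "allOrNothing")) {
  lossType <- match.arg(lossType)
  ids <- intersect(sampleIds(predictionSetTable), sampleIds(labelTable))
  if (length(ids) == 0)
    .stopValidation("no samples in common between prediction sets and labels")
  sets <- predictionSets(predictionSetTable)[ids]
  labs <- labelSets(labelTable)[ids]
  nS <- length(ids)
  sz <- lengths(sets)

  labeled <- lengths(labs) > 0
  lossOf <- function(set, truth) {
    f <- fnrLoss(set, truth)
    if (lossType == "allOrNothing" && f > 0) 1 else f
  }
  losses <- rep(NA_real_, nS)
  losses[labeled] <- mapply(lossOf, sets[labeled], labs[labeled])
  fnr <- if (any(labeled)) 100 * mean(losses[labeled]) else NA_real_

  single <- lengths(labs) == 1
  multi <- lengths(labs) >= 2
  multiFnr <- if (any(multi)) 100 * mean(losses[multi]) else NA_real_

  ## per-class strata over single-label samples
  if (any(single)) {
    cls1 <- vapply(labs[single], `[[`, character(1), 1)
    classes <- if (!is.null(scoreMatrix)) {
      intersect(classNames(scoreMatrix), unique(cls1))
    } else sort(unique(cls1))
    perClass <- do.call(rbind, lapply(classes, function(cl) {
      sel <- which(single)[cls1 == cl]
      fpScore <- NA_real_
      if (!is.null(scoreMatrix)) {
        m <- scores(scoreMatrix)
        fp <- unlist(lapply(sel, function(i) {
          fps <- setdiff(sets[[i]], labs[[i]])
          if (length(fps) > 0 && ids[i] %in% rownames(m)) m[ids[i], fps] else numeric(0)
        }))
        if (length(fp) > 0) fpScore <- mean(fp)
      }
      data.frame(class = cl, n = length(sel),
                 fnr = 100 * mean(losses[sel]),
                 meanSetSize = mean(sz[sel]),
                 meanFalsePositiveScore = fpScore)
    }))
  } else {
    perClass <- data.frame(class = character(0), n = integer(0),
                           fnr = numeric(0), meanSetSize = numeric(0),
                           meanFalsePositiveScore = numeric(0))
  }

  ## exact set compositions
  key <- vapply(sets, paste, character(1), collapse = ";")
  tab <- table(key)
  comp <- data.frame(set = names(tab), count = as.integer(tab))
  comp <- comp[order(-comp$count, comp$set), , drop = FALSE]
  rownames(comp) <- NULL

  ## co-occurrence among multiclass sets
  universe <- if (!is.null(scoreMatrix)) classNames(scoreMatrix) else
    sort(unique(unlist(sets)))
  big <- sets[sz >= 2]
  cooc <- if (length(big) > 0) {
    vapply(universe, function(cl)
      mean(vapply(big, function(s) cl %in% s, logical(1))), numeric(1))
  } else {
    structure(rep(NA_real_, length(universe)), names = universe)
  }

  new("EvalReport",
      overallFnr = fnr, meanSetSize = mean(sz),
      propEmpty = mean(sz == 0), propCertain = mean(sz == 1),
      propUncertain = mean(sz >= 2),
      perClass = perClass, setCompositions = comp, cooccurrence = cooc,
      multiTruthFnr = multiFnr, nSamples = as.integer(nS),
      nLabeled = as.integer(sum(labeled)), nMultiTruth = as.integer(sum(multi)),
      lossType = lossType)
}

## Cross-validation internals ----------------------------------------------

## Flatten labeled samples into per-true-label entry vectors for fast
## subsetting: sIdx/col/w/ts with one entry per (sample, true label).
.cvPrep <- function(scoreMatrix, labelTable) {
  j <- .joinScoresLabels(scoreMatrix, labelTable)
  keep <- lengths(j$labels) > 0
  if (sum(keep) < 2)
    .stopValidation("cross-validation needs at least 2 labeled samples")
  m <- j$mat[keep, , drop = FALSE]
  labs <- j$labels[keep]
  n <- nrow(m)
  len <- lengths(labs)
  sIdx <- rep.int(seq_len(n), len)
  col <- match(unlist(labs, use.names = FALSE), colnames(m))
  list(m = m, labs = labs, n = n,
       sIdx = sIdx, col = col,
       ts = m[cbind(sIdx, col)], w = 1 / len[sIdx],
       singleCol = ifelse(len == 1,
                          vapply(labs, function(l) match(l[1], colnames(m)),
                                 integer(1)),
                          NA_integer_))
}

.makeSplits <- function(n, nRuns, seed) {
  withr::with_seed(as.integer(seed),
                   matrix(replicate(nRuns, sample.int(n)), nrow = n))
}

## One pass of conformal calibrate-and-test over precomputed splits.
## Returns per-run FNR (fraction), mean set size, size-category proportions,
## and pooled per-class loss / size sums over single-label test samples.
.cvRunsConformal <- function(prep, splits, nCal, alpha, lossBound = 1) {
  n <- prep$n
  nRuns <- ncol(splits)
  K <- ncol(prep$m)
  minAlpha <- lossBound / (nCal + 1)
  if (alpha < minAlpha - 1e-12)
    .stopInfeasible(sprintf(
      "alpha = %g is infeasible for calibration size %d: minimum achievable is %g",
      alpha, nCal, minAlpha), minAlpha)
  runFnr <- runSize <- pE <- pC <- pU <- numeric(nRuns)
  runLamhat <- numeric(nRuns)
  clLoss <- clSize <- clN <- numeric(K)
  memb <- logical(n)
  for (r in seq_len(nRuns)) {
    perm <- splits[, r]
    calIdx <- perm[seq_len(nCal)]
    testIdx <- perm[(nCal + 1):n]
    memb[] <- FALSE; memb[calIdx] <- TRUE
    sel <- memb[prep$sIdx]
    lh <- .calibrateLamhat(prep$ts[sel], prep$w[sel], nCal, alpha, lossBound)
    runLamhat[r] <- lh
    ## held-out loss: weighted fraction of true-label scores below lamhat
    selT <- !sel
    runFnr[r] <- sum(prep$w[selT][prep$ts[selT] < lh]) / length(testIdx)
    szT <- rowSums(prep$m[testIdx, , drop = FALSE] >= lh)
    runSize[r] <- mean(szT)
    pE[r] <- mean(szT == 0); pC[r] <- mean(szT == 1); pU[r] <- mean(szT >= 2)
    ## per-class pooling (single-label test samples)
    sc <- prep$singleCol[testIdx]
    ok <- !is.na(sc)
    if (any(ok)) {
      tIdx <- testIdx[ok]; scOk <- sc[ok]
      miss <- as.numeric(prep$m[cbind(tIdx, scOk)] < lh)
      accumulate <- function(values) {
        agg <- rowsum(values, scOk)
        v <- numeric(K)
        v[as.integer(rownames(agg))] <- agg[, 1]
        v
      }
      clLoss <- clLoss + accumulate(miss)
      clSize <- clSize + accumulate(szT[ok])
      clN <- clN + accumulate(rep(1, length(scOk)))
    }
  }
  list(runFnr = runFnr, runSize = runSize, pE = pE, pC = pC, pU = pU,
       lamhat = runLamhat,
       perClass = data.frame(class = colnames(prep$m), n = clN,
                             fnr = ifelse(clN > 0, 100 * clLoss / clN, NA_real_),
                             meanSetSize = ifelse(clN > 0, clSize / clN,
                                                  NA_real_)))
}

## Top-1 baseline over the same test partitions.
.cvRunsTop1 <- function(prep, splits, nCal, floor = 0.5) {
  n <- prep$n
  best <- max.col(prep$m, ties.method = "first")
  bestVal <- prep$m[cbind(seq_len(n), best)]
  setSize <- as.numeric(bestVal >= floor)
  loss <- vapply(seq_len(n), function(i) {
    set <- if (bestVal[i] >= floor) colnames(prep$m)[best[i]] else character(0)
    fnrLoss(set, prep$labs[[i]])
  }, numeric(1))
  nRuns <- ncol(splits)
  runFnr <- runSize <- numeric(nRuns)
  for (r in seq_len(nRuns)) {
    testIdx <- splits[(nCal + 1):n, r]
    runFnr[r] <- mean(loss[testIdx])
    runSize[r] <- mean(setSize[testIdx])
  }
  list(runFnr = runFnr, runSize = runSize)
}

#' Repeated shuffle-split cross-validation of the conformal guarantee
#'
#' In each run the labeled samples are shuffled and split; the conformal
#' predictor is calibrated on the large part (`calFraction`, default 90%) and
#' prediction sets are formed and scored on the held-out rest. Aggregates
#' come with Monte-Carlo standard errors (sd across runs / sqrt(nRuns)).
#' Fully reproducible from `seed`.
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param labelTable a [LabelTable-class]; only labeled samples participate.
#' @param alpha FNR tolerance; must be feasible for the calibration size,
#'   otherwise an error is raised before any run.
#' @param nRuns number of shuffle-split runs.
#' @param calFraction fraction of labeled samples used for calibration
#'   (default 0.9).
#' @param seed integer seed for the shuffles.
#' @param lossBound per-sample loss bound B (default 1).
#' @return a [CrossValResult-class].
#' @export
crossValidate <- function(scoreMatrix, labelTable, alpha, nRuns,
                          calFraction = 0.9, seed = 1, lossBound = 1) {
  stopifnot(nRuns >= 1, calFraction > 0, calFraction < 1)
  prep <- .cvPrep(scoreMatrix, labelTable)
  nCal <- floor(calFraction * prep$n)
  if (nCal < 1 || nCal >= prep$n)
    .stopValidation("calFraction = %g leaves an empty partition for n = %d",
                    calFraction, prep$n)
  splits <- .makeSplits(prep$n, nRuns, seed)
  res <- .cvRunsConformal(prep, splits, nCal, alpha, lossBound)
  runFnr <- 100 * res$runFnr
  perClass <- res$perClass[res$perClass$n > 0, , drop = FALSE]
  rownames(perClass) <- NULL
  new("CrossValResult",
      alpha = alpha, nRuns = as.integer(nRuns),
      calFraction = calFraction, seed = as.integer(seed),
      runFnr = runFnr, runSetSize = res$runSize,
      runPropEmpty = res$pE, runPropCertain = res$pC, runPropUncertain = res$pU,
      meanFnr = mean(runFnr), seFnr = stats::sd(runFnr) / sqrt(nRuns),
      meanSetSize = mean(res$runSize),
      seSetSize = stats::sd(res$runSize) / sqrt(nRuns),
      perClass = perClass)
}

#' Compare conformal prediction sets with the uncalibrated top-1 baseline
#'
#' Runs the shuffle-split harness once per tolerance and scores the
#' uncalibrated top-1 classifier on the identical held-out partitions, so the
#' baseline row is directly comparable (and identical regardless of alpha).
#'
#' @param scoreMatrix a [ScoreMatrix-class].
#' @param labelTable a [LabelTable-class].
#' @param alphas numeric vector of FNR tolerances.
#' @param nRuns shuffle-split runs per method.
#' @param seed integer seed (shared across methods and tolerances).
#' @param calFraction calibration fraction (default 0.9).
#' @param baselineFloor top-1 score floor (default 0.5).
#' @param lossBound per-sample loss bound B (default 1).
#' @return data.frame with columns method, alpha, fnr (percent),
#'   mean_set_size; one row per conformal tolerance plus one baseline row.
#' @export
compareMethods <- function(scoreMatrix, labelTable, alphas, nRuns, seed = 1,
                           calFraction = 0.9, baselineFloor = 0.5,
                           lossBound = 1) {
  stopifnot(length(alphas) >= 1)
  prep <- .cvPrep(scoreMatrix, labelTable)
  nCal <- floor(calFraction * prep$n)
  if (nCal < 1 || nCal >= prep$n)
    .stopValidation("calFraction = %g leaves an empty partition for n = %d",
                    calFraction, prep$n)
  splits <- .makeSplits(prep$n, nRuns, seed)
  rows <- lapply(sort(alphas), function(a) {
    res <- .cvRunsConformal(prep, splits, nCal, a, lossBound)
    data.frame(method = "conformal", alpha = a,
               fnr = 100 * mean(res$runFnr),
               mean_set_size = mean(res$runSize))
  })
  base <- .cvRunsTop1(prep, splits, nCal, baselineFloor)
  rows <- c(rows, list(data.frame(method = "top1_uncalibrated",
                                  alpha = NA_real_,
                                  fnr = 100 * mean(base$runFnr),
                                  mean_set_size = mean(base$runSize))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
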