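test_that("top1Sets applies the floor and breaks argmax ties by column order", {
  m <- matrix(c(0.9, 0.4, 0.6,
                0.2, 0.3, 0.6),
              nrow = 3, ncol = 2,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B")))
  sets <- predictionSets(top1Sets(ScoreMatrix(m)))
  expect_identical(sets[["S1"]], "A")
  expect_identical(sets[["S2"]], character(0))  # max 0.4 below floor
  expect_identical(sets[["S3"]], "A")           # 0.6 vs 0.6 -> first class
})

test_that("fixedThresholdSets honors strict versus closed comparison", {
  m <- matrix(c(0.5, 0.7), 1, 2, dimnames = list("S1", c("A", "B")))
  sm <- ScoreMatrix(m)
  expect_identical(predictionSets(fixedThresholdSets(sm, 0.5, strict = TRUE))[["S1"]],
                   "B")
  expect_identical(predictionSets(fixedThresholdSets(sm, 0.5, strict = FALSE))[["S1"]],
                   c("A", "B"))
  # the score > 1 - alpha comparator at alpha = 0.075
  m2 <- matrix(c(0.93, 0.92), 1, 2, dimnames = list("S1", c("A", "B")))
  expect_identical(
    predictionSets(fixedThresholdSets(ScoreMatrix(m2), 1 - 0.075,
                                      strict = TRUE))[["S1"]],
    "A")
})

test_that("evaluateSets reproduces the validation-cohort arithmetic", {
  fx <- validationFixture()
  report <- evaluateSets(top1Sets(fx$scores, floor = 0.5), fx$labels,
                         scoreMatrix = fx$scores)
  expect_equal(overallFnr(report), 100 * 23 / 257)
  expect_equal(round(overallFnr(report), 2), 8.95)
  expect_equal(sum(setCompositions(report)$count), 257)
  expect_equal(sum(sizeProportions(report)), 1)
})

test_that("evaluateSets separates unknown samples from the FNR", {
  fx <- unknownFixture()
  report <- evaluateSets(top1Sets(fx$scores, floor = 0.5), fx$labels)
  expect_true(is.na(overallFnr(report)))
  expect_equal(report@propEmpty, 29 / 126)
  expect_equal(round(100 * report@propEmpty), 23)
  expect_equal(report@nLabeled, 0L)
})

test_that("full-inclusion sets give zero FNR and set size K", {
  inst <- randomInstance(3)
  K <- length(classNames(inst$scores))
  report <- evaluateSets(fixedThresholdSets(inst$scores, 0, strict = FALSE),
                         inst$labels)
  expect_equal(overallFnr(report), 0)
  expect_equal(meanSetSize(report), K)
})

test_that("multi-truth FNR distinguishes fractional from all-or-nothing loss", {
  m <- matrix(c(0.9, 0.1,
                0.2, 0.3),
              nrow = 2, ncol = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  sm <- ScoreMatrix(m)
  lt <- LabelTable(c("S1", "S2"), list(c("A", "B"), "A"))
  sets <- fixedThresholdSets(sm, 0.5)
  frac <- evaluateSets(sets, lt, lossType = "fractional")
  aon <- evaluateSets(sets, lt, lossType = "allOrNothing")
  # S1 covers A only (loss 0.5 or 1), S2 empty (loss 1)
  expect_equal(overallFnr(frac), 100 * (0.5 + 1) / 2)
  expect_equal(overallFnr(aon), 100)
  expect_equal(frac@multiTruthFnr, 50)
  expect_equal(aon@multiTruthFnr, 100)
})

test_that("per-class strata report FNR, set size and false-positive scores", {
  fx <- validationFixture()
  report <- evaluateSets(top1Sets(fx$scores, floor = 0.5), fx$labels,
                         scoreMatrix = fx$scores)
  pc <- perClass(report)
  expect_setequal(pc$class, paste0("C", 1:5))
  expect_equal(sum(pc$n), 257)
  expect_true(all(pc$fnr >= 0 & pc$fnr <= 100))
  # wrong singletons are the only false positives; they all score 0.9
  expect_equal(mean(pc$meanFalsePositiveScore, na.rm = TRUE), 0.9)
})

test_that("upsetTable mirrors the composition counts", {
  fx <- validationFixture()
  report <- evaluateSets(top1Sets(fx$scores, floor = 0.5), fx$labels)
  up <- upsetTable(report)
  expect_equal(sum(up$count), 257)
  expect_equal(sum(up$count[up$set_size == 0]), 4)
})

test_that("crossValidate is reproducible from its seed and conserves aggregates", {
  sim <- simulateScores(presetAlliumLike(nSamples = 120, seed = 5))
  a <- crossValidate(sim$scores, sim$labels, alpha = 0.2, nRuns = 5, seed = 42)
  b <- crossValidate(sim$scores, sim$labels, alpha = 0.2, nRuns = 5, seed = 42)
  expect_identical(a@runFnr, b@runFnr)
  expect_identical(a@runSetSize, b@runSetSize)
  expect_equal(overallFnr(a), mean(a@runFnr))
  expect_equal(meanSetSize(a), mean(a@runSetSize))
  expect_equal(a@seFnr, stats::sd(a@runFnr) / sqrt(5))
})

test_that("a perfect classifier cross-validates to zero FNR and singleton sets", {
  pf <- perfectFixture(n = 40)
  cv <- crossValidate(pf$scores, pf$labels, alpha = 0.2, nRuns = 10, seed = 1)
  expect_equal(overallFnr(cv), 0)
  expect_equal(meanSetSize(cv), 1)
  expect_true(all(cv@runPropCertain == 1))
})

test_that("infeasible alpha fails before any cross-validation run", {
  pf <- perfectFixture(n = 10)  # nCal = 9 -> minimum alpha 0.1
  expect_error(crossValidate(pf$scores, pf$labels, alpha = 0.05, nRuns = 3,
                             seed = 1),
               "infeasible", class = "setconformInfeasibleAlphaError")
})

test_that("decreasing alpha never raises the FNR nor shrinks sets on fixed splits", {
  sim <- simulateScores(presetAlliumLike(nSamples = 300, seed = 9))
  alphas <- c(0.075, 0.1, 0.15, 0.2, 0.3)
  cvs <- lapply(alphas, function(a)
    crossValidate(sim$scores, sim$labels, alpha = a, nRuns = 20, seed = 77))
  fnrs <- vapply(cvs, overallFnr, numeric(1))
  sizes <- vapply(cvs, meanSetSize, numeric(1))
  expect_false(is.unsorted(fnrs))        # FNR nondecreasing with alpha
  expect_false(is.unsorted(rev(sizes)))  # set size nonincreasing with alpha
})

test_that("compareMethods reports a constant baseline and a guarantee-bound conformal row", {
  pf <- perfectFixture(n = 60)
  tab <- compareMethods(pf$scores, pf$labels, alphas = c(0.1, 0.2),
                        nRuns = 5, seed = 2)
  expect_true(all(tab$fnr == 0))

  sim <- simulateScores(miscalibratedSpec())
  tab2 <- compareMethods(sim$scores, sim$labels, alphas = c(0.075, 0.15, 0.3),
                         nRuns = 50, seed = 13)
  base <- tab2[tab2$method == "top1_uncalibrated", ]
  expect_equal(nrow(base), 1)
  conf <- tab2[tab2$method == "conformal", ]
  # deliberately miscalibrated classifier: baseline misses > 7.5%, the
  # conformal row at the matching tolerance does not
  expect_gt(base$fnr, 7.5)
  expect_lt(conf$fnr[conf$alpha == 0.075], base$fnr)
})
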