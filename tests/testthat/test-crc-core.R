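test_that("fnrLoss is the fraction of true labels missed", {
  expect_equal(fnrLoss(c("A", "B"), "A"), 0)
  expect_equal(fnrLoss(character(0), "A"), 1)
  expect_equal(fnrLoss("A", c("A", "B")), 0.5)
  expect_error(fnrLoss("A", character(0)), "nonempty",
               class = "setconformValidationError")
})

test_that("empiricalFnr matches hand-enumerated losses and its boundary cases", {
  fx <- toyFixture()
  expect_equal(empiricalFnr(0, fx$scores, fx$labels), 0)
  # true scores 0.9/0.8/0.7/0.6: threshold 0.75 misses two of four
  expect_equal(empiricalFnr(0.75, fx$scores, fx$labels), 0.5)
  expect_equal(empiricalFnr(1, fx$scores, fx$labels), 1)  # above max score 0.9
})

test_that("calibrate reproduces the worked examples", {
  fx <- toyFixture()
  # zero calibration misses allowed: (4/5)*0 + 1/5 <= 0.2
  expect_equal(lamhat(calibrate(fx$scores, fx$labels, alpha = 0.2)), 0.6)
  # one miss allowed: (4/5)*(1/4) + 1/5 = 0.4 <= 0.4
  expect_equal(lamhat(calibrate(fx$scores, fx$labels, alpha = 0.4)), 0.7)

  pf <- perfectFixture()
  m <- calibrate(pf$scores, pf$labels, alpha = 0.2)
  expect_equal(lamhat(m), 1.0)

  err <- tryCatch(calibrate(fx$scores, fx$labels, alpha = 0.19),
                  setconformInfeasibleAlphaError = identity)
  expect_s3_class(err, "setconformInfeasibleAlphaError")
  expect_equal(err$minAlpha, 0.2)  # reported minimum achievable tolerance
})

test_that("minFeasibleAlpha is B/(n+1)", {
  expect_equal(minFeasibleAlpha(4), 0.2)
  expect_equal(minFeasibleAlpha(999), 0.001)
  expect_equal(minFeasibleAlpha(1), 0.5)
  expect_equal(minFeasibleAlpha(9, lossBound = 0.5), 0.05)
})

test_that("formSets applies the closed inclusion rule per sample", {
  m <- matrix(c(0.96, 0.2, 0.0,
                0.85, 0.3, 0.0,
                0.01, 0.1, 0.0),
              nrow = 3, ncol = 3, byrow = FALSE,
              dimnames = list(c("S1", "S2", "S3"), c("A", "B", "C")))
  # S1 carries the confusable-pair pattern: 0.96 and 0.85 both pass 0.5
  sm <- ScoreMatrix(m)
  model <- CalibratedModel(alpha = 0.1, lamhat = 0.5, nCal = 100,
                           classNames = c("A", "B", "C"))
  sets <- formSets(sm, model)
  ps <- predictionSets(sets)
  expect_identical(ps[["S1"]], c("A", "B"))
  expect_identical(unname(sizeCategory(sets))[1], "uncertain")
  expect_identical(ps[["S2"]], character(0))  # (0.2, 0.3, 0.1) all below
  zero <- CalibratedModel(alpha = 0.1, lamhat = 0, nCal = 100,
                          classNames = c("A", "B", "C"))
  expect_true(all(lengths(predictionSets(formSets(sm, zero))) == 3))

  missing <- CalibratedModel(alpha = 0.1, lamhat = 0.5, nCal = 100,
                             classNames = c("A", "B", "D"))
  expect_error(formSets(sm, missing), "D", class = "setconformValidationError")
})

test_that("riskCurve satisfies its structural invariants", {
  fx <- toyFixture()
  rc <- riskCurve(fx$scores, fx$labels)
  tab <- asTable(rc)
  expect_identical(names(tab),
                   c("threshold", "empirical_risk", "adjusted_risk"))
  expect_false(is.unsorted(tab$threshold, strictly = TRUE))
  expect_false(is.unsorted(tab$empirical_risk))
  n <- nCal(rc)
  expect_equal(tab$adjusted_risk,
               tab$empirical_risk * n / (n + 1) + lossBound(rc) / (n + 1))
  # candidates are 0 plus the unique true-label scores
  expect_equal(tab$threshold, c(0, 0.6, 0.7, 0.8, 0.9))
  expect_equal(tab$empirical_risk, c(0, 0, 0.25, 0.5, 0.75))
})

test_that("calibrated lamhat equals the dense-grid supremum on random instances", {
  for (seed in 1:50) {
    inst <- randomInstance(seed)
    n <- sum(lengths(labelSets(inst$labels)) > 0)
    alpha <- withr::with_seed(seed + 1000, runif(1, minFeasibleAlpha(n), 0.9))
    got <- lamhat(calibrate(inst$scores, inst$labels, alpha))
    want <- bruteForceLamhat(inst$scores, inst$labels, alpha)
    expect_lte(abs(got - want), 1e-4 + 1e-12)
  }
})

test_that("lamhat is monotone in alpha and sets are nested across thresholds", {
  inst <- randomInstance(99)
  grid <- seq(0.1, 0.9, by = 0.1)
  lams <- vapply(grid, function(a)
    lamhat(calibrate(inst$scores, inst$labels, a)), numeric(1))
  expect_false(is.unsorted(lams))

  lo <- formSets(inst$scores, CalibratedModel(0.5, min(lams), 50,
                                              classNames(inst$scores)))
  hi <- formSets(inst$scores, CalibratedModel(0.5, max(lams), 50,
                                              classNames(inst$scores)))
  nested <- mapply(function(a, b) all(a %in% b),
                   predictionSets(hi), predictionSets(lo))
  expect_true(all(nested))
})

test_that("empiricalFnr is nondecreasing in the threshold", {
  inst <- randomInstance(7)
  grid <- seq(0, 1, by = 0.05)
  fnrs <- vapply(grid, empiricalFnr, numeric(1),
                 scoreMatrix = inst$scores, labelTable = inst$labels)
  expect_false(is.unsorted(fnrs))
})
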