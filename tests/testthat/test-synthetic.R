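test_that("simulation is deterministic in its seed", {
  spec <- presetAlliumLike(nSamples = 200, seed = 17)
  a <- simulateScores(spec)
  b <- simulateScores(spec)
  expect_identical(scores(a$scores), scores(b$scores))
  expect_identical(labelSets(a$labels), labelSets(b$labels))
  c <- simulateScores(spec, seed = 18)
  expect_false(identical(scores(a$scores), scores(c$scores)))
})

test_that("all-OOD specs yield empty truth and background-only scores", {
  spec <- presetAlliumLike(nSamples = 100, seed = 2)
  spec@oodFraction <- 1
  spec@multiTruthFraction <- 0
  sim <- simulateScores(spec)
  expect_true(all(lengths(labelSets(sim$labels)) == 0))
  # background Beta(0.5, 10) essentially never reaches 0.9
  expect_lt(max(scores(sim$scores)), 0.9)
})

test_that("spec invariants are enforced before sampling", {
  expect_error(simulationSpec(c("A", "B"), c(0.6, 0.6)), "sum to 1")
  expect_error(simulationSpec(c("A", "B"), c(0.5, 0.5),
                              multiTruthFraction = 0.8, oodFraction = 0.3))
  spec <- presetAlliumLike()
  spec@oodFraction <- 1.5
  expect_error(simulateScores(spec))
})

test_that("scores stay in [0,1] and class frequencies match the spec", {
  spec <- presetAlliumLike(nSamples = 10000, seed = 4)
  spec@oodFraction <- 0
  spec@multiTruthFraction <- 0
  sim <- simulateScores(spec)
  s <- scores(sim$scores)
  expect_true(all(s >= 0 & s <= 1))
  truth <- unlist(labelSets(sim$labels))
  counts <- table(factor(truth, levels = classNames(spec)))
  gof <- stats::chisq.test(counts, p = spec@classFrequencies)
  expect_gt(gof$p.value, 0.001)
})

test_that("a concentrated, confusion-free spec supports near-zero top-1 FNR", {
  spec <- simulationSpec(classNames = paste0("k", 1:5),
                         classFrequencies = rep(0.2, 5),
                         onTargetShape = c(200, 1),  # scores hug 1
                         nSamples = 10000, seed = 6)
  sim <- simulateScores(spec)
  report <- evaluateSets(top1Sets(sim$scores), sim$labels)
  expect_lte(overallFnr(report), 1)
})

test_that("confusable classes inflate set sizes under the preset", {
  spec <- presetAlliumLike(nSamples = 10000, seed = 8)
  sim <- simulateScores(spec)
  report <- evaluateSets(fixedThresholdSets(sim$scores, 0.5), sim$labels,
                         scoreMatrix = sim$scores)
  pc <- perClass(report)
  confused <- c("PAX5 P80R", "PAX5alt", "BCR::ABL1", "BCR::ABL1-like")
  plain <- setdiff(pc$class, confused)
  expect_gt(mean(pc$meanSetSize[pc$class %in% confused]),
            mean(pc$meanSetSize[pc$class %in% plain]))
})

test_that("the preset validates and covers its classes at cohort scale", {
  spec <- presetAlliumLike(nSamples = 851, seed = 1)
  expect_true(validObject(spec, test = TRUE))
  sim <- simulateScores(spec)
  observed <- unique(unlist(labelSets(sim$labels)))
  expect_gte(length(observed), 1)
  expect_lte(length(observed), 14)
  expect_true(all(observed %in% classNames(spec)))
})
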