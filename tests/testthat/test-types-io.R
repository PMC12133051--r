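test_that("score tables round-trip value-for-value in both dialects", {
  fx <- toyFixture()
  for (ext in c(".csv", ".tsv")) {
    f <- withr::local_tempfile(fileext = ext)
    writeScores(fx$scores, f)
    back <- readScores(f)
    expect_identical(scores(back), scores(fx$scores))
    expect_identical(sampleIds(back), sampleIds(fx$scores))
    expect_identical(classNames(back), classNames(fx$scores))
  }
})

test_that("score reading validates range, duplicates and numeric cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,A,B", "S1,0.5,0.5", "S2,1.2,0.1"), f)
  expect_error(readScores(f), "S2.*A.*1\\.2", class = "setconformValidationError")

  writeLines(c("sample_id,A,B", "S1,0.5,0.5", "S1,0.4,0.1"), f)
  expect_error(readScores(f), "duplicate", class = "setconformValidationError")

  writeLines(c("sample_id,A,B", "S1,0.5,high"), f)
  expect_error(readScores(f), "non-numeric.*S1.*B",
               class = "setconformValidationError")
})

test_that("label tables parse multi-label cells and the unknown sentinel", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,true_labels", "S1,A;B", "S2,unknown", "S3,"), f)
  lt <- readLabels(f)
  labs <- labelSets(lt)
  expect_identical(labs[["S1"]], c("A", "B"))
  expect_identical(labs[["S2"]], character(0))
  expect_identical(labs[["S3"]], character(0))

  writeLines(c("sample_id,true_labels", "S1,A", "S1,B"), f)
  expect_error(readLabels(f), "duplicate", class = "setconformValidationError")
})

test_that("label tables round-trip, preserving empty sets", {
  lt <- LabelTable(c("S1", "S2", "S3"),
                   list(c("A", "B"), character(0), "B"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeLabels(lt, f)
  back <- readLabels(f)
  expect_identical(labelSets(back), labelSets(lt))
})

test_that("joining labels to scores fails loudly on foreign class names", {
  fx <- toyFixture()
  badLabels <- LabelTable(paste0("S", 1:4), rep("Z", 4))
  expect_error(calibrate(fx$scores, badLabels, 0.3), "Z",
               class = "setconformValidationError")
})

test_that("model files round-trip field-for-field and reject malformed input", {
  model <- CalibratedModel(alpha = 0.1, lamhat = 0.62, nCal = 765,
                           classNames = c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".yaml")
  writeModel(model, f)
  back <- readModel(f)
  expect_equal(back@alpha, model@alpha)
  expect_equal(back@lamhat, model@lamhat)
  expect_identical(back@nCal, model@nCal)
  expect_equal(back@lossBound, model@lossBound)
  expect_identical(back@classNames, model@classNames)
  expect_identical(back@inclusionRule, model@inclusionRule)

  obj <- yaml::read_yaml(f)
  obj$lamhat <- NULL
  yaml::write_yaml(obj, f)
  expect_error(readModel(f), "lamhat", class = "setconformValidationError")
})

test_that("a model violating the feasibility invariant refuses to load", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(format_version = 1, alpha = 0.1, lamhat = 0.5,
                        n_cal = 4, loss_bound = 1,
                        inclusion_rule = "score >= lamhat",
                        class_names = list("A", "B")), f)
  expect_error(readModel(f), "feasibility", class = "setconformValidationError")
  expect_error(CalibratedModel(alpha = 0.1, lamhat = 0.5, nCal = 4,
                               classNames = c("A", "B")))
})

test_that("prediction-set tables round-trip with size categories intact", {
  pst <- PredictionSetTable(c("S1", "S2", "S3"),
                            list(c("A", "B"), character(0), "B"))
  expect_identical(unname(sizeCategory(pst)),
                   c("uncertain", "empty", "certain"))
  f <- withr::local_tempfile(fileext = ".csv")
  writePredictionSets(pst, f)
  back <- readPredictionSets(f)
  expect_identical(predictionSets(back), predictionSets(pst))
  expect_identical(sizeCategory(back), sizeCategory(pst))
  tab <- utils::read.csv(f)
  expect_identical(names(tab),
                   c("sample_id", "prediction_set", "set_size",
                     "size_category"))
})

test_that("ScoreMatrix validity rejects out-of-range and duplicate input", {
  m <- matrix(c(0.5, 0.5, 1.2, 0.1), 2, 2,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  expect_error(ScoreMatrix(m), "S1.*B.*1\\.2")
  m2 <- matrix(0.5, 2, 2, dimnames = list(c("S1", "S1"), c("A", "B")))
  expect_error(ScoreMatrix(m2), "duplicate")
})

test_that("simulation specs round-trip through the structured config", {
  spec <- presetAlliumLike(nSamples = 101, seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeSimulationSpec(spec, f)
  back <- readSimulationSpec(f)
  expect_equal(back@classFrequencies, spec@classFrequencies)
  expect_equal(back@confusionWeights, spec@confusionWeights)
  expect_identical(back@nSamples, spec@nSamples)
  expect_identical(back@seed, spec@seed)
  simA <- simulateScores(spec)
  simB <- simulateScores(back)
  expect_identical(scores(simA$scores), scores(simB$scores))
})
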