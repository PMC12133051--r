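# Fixtures are built in code; nothing is read from disk.

# Four single-label samples whose true-class scores are 0.9/0.8/0.7/0.6 and
# whose off-class scores stay below 0.5.
toyFixture <- function() {
  m <- matrix(c(0.9, 0.8, 0.7, 0.6,
                0.1, 0.2, 0.1, 0.3),
              nrow = 4, ncol = 2,
              dimnames = list(paste0("S", 1:4), c("A", "B")))
  list(scores = ScoreMatrix(m),
       labels = LabelTable(paste0("S", 1:4), rep("A", 4)))
}

# A deterministic perfect classifier: true class scores exactly 1, rest 0.
perfectFixture <- function(n = 20, K = 4) {
  cls <- LETTERS[seq_len(K)]
  truth <- rep(cls, length.out = n)
  m <- matrix(0, n, K, dimnames = list(sprintf("P%03d", seq_len(n)), cls))
  m[cbind(seq_len(n), match(truth, cls))] <- 1
  list(scores = ScoreMatrix(m), labels = LabelTable(rownames(m), truth))
}

# Validation-cohort arithmetic fixture: of 257 single-label samples the top-1
# rule at floor 0.5 yields 234 correct singletons, 19 wrong singletons and 4
# empty sets.
validationFixture <- function() {
  cls <- paste0("C", 1:5)
  n <- 257
  m <- matrix(0.05, n, 5, dimnames = list(sprintf("V%03d", seq_len(n)), cls))
  truth <- rep(cls, length.out = n)
  ti <- match(truth, cls)
  correct <- 1:234
  wrong <- 235:253
  empty <- 254:257
  m[cbind(correct, ti[correct])] <- 0.9
  wrongCol <- ifelse(ti[wrong] == 1L, 2L, 1L)
  m[cbind(wrong, wrongCol)] <- 0.9
  m[cbind(wrong, ti[wrong])] <- 0.1
  m[empty, ] <- 0.2
  list(scores = ScoreMatrix(m), labels = LabelTable(rownames(m), truth))
}

# Unknown-subtype cohort arithmetic fixture: 126 samples with empty truth of
# which 97 have a top score reaching 0.5 and 29 have all-low scores.
unknownFixture <- function() {
  cls <- paste0("C", 1:5)
  n <- 126
  m <- matrix(0.05, n, 5, dimnames = list(sprintf("U%03d", seq_len(n)), cls))
  m[cbind(1:97, rep(1:5, length.out = 97))] <- 0.8
  m[98:126, ] <- 0.1
  list(scores = ScoreMatrix(m),
       labels = LabelTable(rownames(m), replicate(n, character(0),
                                                  simplify = FALSE)))
}

# Random small calibration instances (n <= 50, K <= 6, 1-2 true labels).
randomInstance <- function(seed) {
  withr::with_seed(seed, {
    n <- sample(2:50, 1)
    K <- sample(2:6, 1)
    cls <- LETTERS[seq_len(K)]
    m <- matrix(runif(n * K), n, K,
                dimnames = list(sprintf("R%03d", seq_len(n)), cls))
    labs <- lapply(seq_len(n), function(i)
      sample(cls, sample(1:min(2, K), 1)))
    list(scores = ScoreMatrix(m), labels = LabelTable(rownames(m), labs))
  })
}

# Independent dense-grid oracle for the calibrated threshold: evaluates the
# adjusted risk at 10,001 evenly spaced thresholds directly from the loss
# definition (a class is in the set iff its score >= t) and returns the
# largest feasible grid point. NA when no grid point is feasible.
bruteForceLamhat <- function(scoreMatrix, labelTable, alpha, lossBound = 1,
                             gridN = 10001) {
  m <- scores(scoreMatrix)
  labs <- labelSets(labelTable)[rownames(m)]
  keep <- lengths(labs) > 0
  m <- m[keep, , drop = FALSE]
  labs <- labs[keep]
  n <- nrow(m)
  grid <- seq(0, 1, length.out = gridN)
  lossAt <- vapply(seq_len(n), function(i) {
    ts <- m[i, labs[[i]]]
    # per grid point: fraction of true labels whose score misses the cut
    colMeans(outer(ts, grid, "<"))
  }, numeric(gridN))
  riskGrid <- rowMeans(matrix(lossAt, nrow = gridN))
  adjusted <- riskGrid * n / (n + 1) + lossBound / (n + 1)
  feasible <- which(adjusted <= alpha + 1e-12)
  if (length(feasible) == 0) return(NA_real_)
  grid[max(feasible)]
}

# A deliberately confusion-heavy simulated classifier whose uncalibrated
# top-1 baseline misses well over 7.5% of true labels.
miscalibratedSpec <- function(nSamples = 600, seed = 11) {
  cls <- paste0("sub", 1:6)
  w <- matrix(0, 6, 6, dimnames = list(cls, cls))
  w["sub1", "sub2"] <- 0.9
  w["sub2", "sub1"] <- 0.9
  w["sub3", "sub4"] <- 0.9
  simulationSpec(classNames = cls,
                 classFrequencies = rep(1 / 6, 6),
                 confusionWeights = w,
                 onTargetShape = c(8, 2),    # diffuse truth scores
                 offTargetShape = c(0.5, 10),
                 confusedShape = c(8, 2),    # confusers match the truth
                 multiTruthFraction = 0.15, oodFraction = 0,
                 nSamples = nSamples, seed = seed)
}
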