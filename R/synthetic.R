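## Synthetic classifier-score generator. Emulates the statistical structure
## of RNA-seq subtype classifier outputs: imbalanced class frequencies,
## one-vs-rest scores (rows are not simplexes), confusable class pairs where
## two classes score high simultaneously, a small fraction of samples with
## two true subtypes, and out-of-distribution samples whose scores are all
## background draws.

#' Construct a SimulationSpec
#'
#' @param classNames character class labels (K >= 2).
#' @param classFrequencies probability vector of length K.
#' @param confusionWeights K x K matrix in \[0,1\] (rows = true class; entry
#'   (j,k) = probability that class k draws a confused score under true class
#'   j; diagonal zero). Default: no confusion.
#' @param onTargetShape,offTargetShape,confusedShape beta shape pairs for the
#'   true-class, background and confusable-class score distributions.
#' @param multiTruthFraction fraction of samples with two true labels.
#' @param oodFraction fraction of out-of-distribution samples (empty truth).
#' @param nSamples rows to generate.
#' @param seed integer seed.
#' @return a validated [SimulationSpec-class].
#' @seealso [presetAlliumLike()], [simulateScores()]
#' @export
simulationSpec <- function(classNames, classFrequencies,
                           confusionWeights = NULL,
                           onTargetShape = c(24, 1),
                           offTargetShape = c(0.5, 10),
                           confusedShape = c(17, 3),
                           multiTruthFraction = 0, oodFraction = 0,
                           nSamples = 1000L, seed = 1L) {
  K <- length(classNames)
  if (is.null(confusionWeights)) {
    confusionWeights <- matrix(0, K, K, dimnames = list(classNames, classNames))
  }
  new("SimulationSpec",
      classNames = as.character(classNames),
      classFrequencies = as.numeric(classFrequencies),
      confusionWeights = confusionWeights,
      onTargetShape = as.numeric(onTargetShape),
      offTargetShape = as.numeric(offTargetShape),
      confusedShape = as.numeric(confusedShape),
      multiTruthFraction = as.numeric(multiTruthFraction),
      oodFraction = as.numeric(oodFraction),
      nSamples = as.integer(nSamples), seed = as.integer(seed))
}

#' Preset emulating an ALL-subtype classifier's output structure
#'
#' A documented, illustrative parameterization with 14 imbalanced leukemia
#' subtype labels, two built-in confusable pairs (PAX5 P80R vs PAX5alt and
#' BCR::ABL1 vs BCR::ABL1-like), on-target scores concentrated near 0.96,
#' confusable-class scores near 0.85, low background scores, ~5% samples with
#' two true subtypes and ~5% out-of-distribution samples. Every number is
#' this generator's own choice, mimicking the qualitative structure of real
#' subtype classifiers, not measured values of any particular cohort.
#'
#' @param nSamples rows to generate (default 851).
#' @param seed integer seed (default 1).
#' @return a [SimulationSpec-class].
#' @export
presetAlliumLike <- function(nSamples = 851L, seed = 1L) {
  cls <- c("high hyperdiploid", "ETV6::RUNX1", "DUX4-r", "PAX5alt",
           "BCR::ABL1-like", "KMT2A-r", "TCF3::PBX1", "BCR::ABL1",
           "ZNF384-r", "iAMP21", "MEF2D-r", "PAX5 P80R",
           "low hypodiploid", "NUTM1-r")
  freq <- c(0.22, 0.20, 0.08, 0.07, 0.07, 0.06, 0.06, 0.05,
            0.05, 0.04, 0.03, 0.03, 0.02, 0.02)
  w <- matrix(0, 14, 14, dimnames = list(cls, cls))
  w["PAX5 P80R", "PAX5alt"] <- 0.80
  w["PAX5alt", "PAX5 P80R"] <- 0.30
  w["BCR::ABL1", "BCR::ABL1-like"] <- 0.60
  w["BCR::ABL1-like", "BCR::ABL1"] <- 0.60
  simulationSpec(classNames = cls, classFrequencies = freq,
                 confusionWeights = w,
                 onTargetShape = c(24, 1),    # mean 0.96
                 offTargetShape = c(0.5, 10), # mean ~0.05 background
                 confusedShape = c(17, 3),    # mean 0.85
                 multiTruthFraction = 0.05, oodFraction = 0.05,
                 nSamples = nSamples, seed = seed)
}

#' Simulate a classifier score matrix with known truth
#'
#' Draws `nSamples` rows. Each non-OOD sample draws its true label(s) from
#' the class frequencies (multi-truth samples draw a second, distinct label);
#' true-label scores come from the on-target beta distribution; every
#' off-target class draws from the confused distribution with the probability
#' given by the confusion weights (maximum over the sample's true classes),
#' otherwise from the background distribution. OOD samples have empty truth
#' and all-background scores. All draws flow through one stream seeded by
#' `spec@seed` (or the `seed` override), so identical seeds give identical
#' output.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed optional integer overriding `spec@seed`.
#' @return list with elements `scores` (a [ScoreMatrix-class]) and `labels`
#'   (a [LabelTable-class]).
#' @export
simulateScores <- function(spec, seed = NULL) {
  stopifnot(is(spec, "SimulationSpec"))
  validObject(spec)
  if (is.null(seed)) seed <- spec@seed
  K <- length(spec@classNames)
  n <- spec@nSamples
  withr::with_seed(as.integer(seed), {
    kind <- sample(c("ood", "multi", "single"), n, replace = TRUE,
                   prob = c(spec@oodFraction, spec@multiTruthFraction,
                            1 - spec@oodFraction - spec@multiTruthFraction))
    m <- matrix(stats::rbeta(n * K, spec@offTargetShape[1],
                             spec@offTargetShape[2]),
                n, K, dimnames = list(sprintf("sample_%04d", seq_len(n)),
                                      spec@classNames))
    labs <- vector("list", n)
    for (i in seq_len(n)) {
      if (kind[i] == "ood") {
        labs[[i]] <- character(0)
        next
      }
      first <- sample.int(K, 1, prob = spec@classFrequencies)
      truth <- first
      if (kind[i] == "multi") {
        p2 <- spec@classFrequencies
        p2[first] <- 0
        truth <- c(first, sample.int(K, 1, prob = p2))
      }
      labs[[i]] <- spec@classNames[truth]
      m[i, truth] <- stats::rbeta(length(truth), spec@onTargetShape[1],
                                  spec@onTargetShape[2])
      off <- setdiff(seq_len(K), truth)
      pConf <- apply(spec@confusionWeights[truth, off, drop = FALSE], 2, max)
      hit <- off[stats::runif(length(off)) < pConf]
      if (length(hit) > 0)
        m[i, hit] <- stats::rbeta(length(hit), spec@confusedShape[1],
                                  spec@confusedShape[2])
    }
    list(scores = ScoreMatrix(m), labels = LabelTable(rownames(m), labs))
  })
}
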