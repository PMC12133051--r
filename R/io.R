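## Delimited-text and structured-text exchange formats.
## Score/label/prediction-set tables are plain delimited text with a header;
## models, reports and simulation specs persist as YAML with a format-version
## field so a deployed threshold stays human-auditable.

.MODEL_FORMAT_VERSION <- 1L

.resolveSep <- function(path, sep) {
  if (!identical(sep, "auto")) return(sep)
  if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a classifier score table
#'
#' Reads a delimited text file whose first column holds sample identifiers and
#' whose remaining columns hold per-class scores in \[0,1\]. Row and column
#' order are preserved. Comma and tab dialects are both accepted; the
#' delimiter is auto-detected from the extension (`.tsv`/`.tab`/`.txt` = tab,
#' otherwise comma) and can be overridden.
#'
#' @param path file to read.
#' @param sep "auto" (default), "," or "\t".
#' @return a validated [ScoreMatrix-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("sample_id,A,B", "S1,0.9,0.1", "S2,0.2,0.8"), f)
#' readScores(f)
#' @export
readScores <- function(path, sep = "auto") {
  if (!file.exists(path)) .stopValidation("score file not found: %s", path)
  sep <- .resolveSep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 3)
    .stopValidation("score table needs a sample id column and >= 2 class columns")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    .stopValidation("duplicate sample id in %s: '%s'", path,
                    ids[duplicated(ids)][1])
  cls <- colnames(df)[-1]
  m <- matrix(NA_real_, nrow(df), length(cls), dimnames = list(ids, cls))
  for (j in seq_along(cls)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]))
    if (length(bad) > 0)
      .stopValidation("non-numeric score for sample '%s', class '%s': '%s'",
                      ids[bad[1]], cls[j], df[[j + 1]][bad[1]])
    m[, j] <- v
  }
  out <- which(!is.finite(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(out) > 0)
    .stopValidation("score out of [0,1] for sample '%s', class '%s': %s",
                    ids[out[1, 1]], cls[out[1, 2]], format(m[out[1, 1], out[1, 2]]))
  ScoreMatrix(m)
}

#' Write a classifier score table
#'
#' @param x a [ScoreMatrix-class].
#' @param path destination file.
#' @param sep "auto" (by extension), "," or "\t".
#' @return `path`, invisibly.
#' @export
writeScores <- function(x, path, sep = "auto") {
  stopifnot(is(x, "ScoreMatrix"))
  sep <- .resolveSep(path, sep)
  df <- data.frame(sample_id = sampleIds(x),
                   as.data.frame(scores(x), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label table
#'
#' Reads a two-column delimited file: sample id and a delimiter-joined list of
#' true class labels. An empty cell or the sentinel "unknown" encodes an
#' unknown subtype (empty label set).
#'
#' @param path file to read.
#' @param sep table delimiter ("auto", "," or "\t").
#' @param labelSep separator inside the label cell (default ";").
#' @return a validated [LabelTable-class].
#' @export
readLabels <- function(path, sep = "auto", labelSep = ";") {
  if (!file.exists(path)) .stopValidation("label file not found: %s", path)
  sep <- .resolveSep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  if (ncol(df) < 2)
    .stopValidation("label table needs columns sample_id and true_labels")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    .stopValidation("duplicate sample id in %s: '%s'", path,
                    ids[duplicated(ids)][1])
  labs <- lapply(df[[2]], function(cell) {
    if (is.na(cell) || cell == "" || tolower(cell) == "unknown") return(character(0))
    parts <- strsplit(cell, labelSep, fixed = TRUE)[[1]]
    parts <- trimws(parts)
    parts[nzchar(parts)]
  })
  LabelTable(ids, labs)
}

#' Write a label table
#'
#' @param x a [LabelTable-class].
#' @param path destination file.
#' @param sep table delimiter ("auto", "," or "\t").
#' @param labelSep separator inside the label cell (default ";").
#' @return `path`, invisibly.
#' @export
writeLabels <- function(x, path, sep = "auto", labelSep = ";") {
  stopifnot(is(x, "LabelTable"))
  sep <- .resolveSep(path, sep)
  cells <- vapply(x@labels, function(l) {
    if (length(l) == 0) "unknown" else paste(l, collapse = labelSep)
  }, character(1))
  df <- data.frame(sample_id = x@sampleIds, true_labels = cells)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a prediction-set table
#'
#' Emits the header `sample_id,prediction_set,set_size,size_category` with
#' ";"-joined sets (empty string for the empty set).
#'
#' @param x a [PredictionSetTable-class].
#' @param path destination file.
#' @param sep table delimiter ("auto", "," or "\t").
#' @param labelSep separator inside the set cell (default ";").
#' @return `path`, invisibly.
#' @export
writePredictionSets <- function(x, path, sep = "auto", labelSep = ";") {
  stopifnot(is(x, "PredictionSetTable"))
  sep <- .resolveSep(path, sep)
  utils::write.table(asTable(x, labelSep = labelSep), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction-set table
#'
#' @param path file written by [writePredictionSets()].
#' @param sep table delimiter ("auto", "," or "\t").
#' @param labelSep separator inside the set cell (default ";").
#' @return a [PredictionSetTable-class].
#' @export
readPredictionSets <- function(path, sep = "auto", labelSep = ";") {
  if (!file.exists(path)) .stopValidation("prediction-set file not found: %s", path)
  sep <- .resolveSep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", na.strings = NULL)
  sets <- lapply(df[["prediction_set"]], function(cell) {
    if (is.na(cell) || cell == "") return(character(0))
    strsplit(cell, labelSep, fixed = TRUE)[[1]]
  })
  PredictionSetTable(df[[1]], sets)
}

#' Persist a calibrated model
#'
#' Writes a human-readable YAML file carrying alpha, lamhat (full precision),
#' the calibration size, loss bound, class list, inclusion rule and a format
#' version, so a deployed threshold can be audited.
#'
#' @param model a [CalibratedModel-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "CalibratedModel"))
  obj <- list(format_version = .MODEL_FORMAT_VERSION,
              alpha = model@alpha,
              lamhat = model@lamhat,
              n_cal = model@nCal,
              loss_bound = model@lossBound,
              inclusion_rule = model@inclusionRule,
              class_names = as.list(model@classNames))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Load a calibrated model
#'
#' Fails with a message listing the missing fields on a malformed file, and
#' refuses to load a model violating the feasibility invariant
#' alpha >= B/(n_cal + 1).
#'
#' @param path file written by [writeModel()].
#' @return a validated [CalibratedModel-class].
#' @export
readModel <- function(path) {
  if (!file.exists(path)) .stopValidation("model file not found: %s", path)
  obj <- tryCatch(yaml::read_yaml(path), error = function(e)
    .stopValidation("model file is not parseable YAML: %s", conditionMessage(e)))
  need <- c("format_version", "alpha", "lamhat", "n_cal", "loss_bound",
            "inclusion_rule", "class_names")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0)
    .stopValidation("model file %s is missing fields: %s", path,
                    paste(missing, collapse = ", "))
  if (obj$format_version > .MODEL_FORMAT_VERSION)
    .stopValidation("model format version %s is newer than supported (%d)",
                    obj$format_version, .MODEL_FORMAT_VERSION)
  tryCatch(
    CalibratedModel(alpha = obj$alpha, lamhat = obj$lamhat, nCal = obj$n_cal,
                    classNames = unlist(obj$class_names),
                    lossBound = obj$loss_bound),
    error = function(e) .stopValidation("invalid model in %s: %s", path,
                                        conditionMessage(e)))
}

## Tabular exports ---------------------------------------------------------

#' Tabular views of setconform objects
#'
#' `asTable` renders the package's S4 containers as plain data.frames suitable
#' for writing as delimited text: prediction sets as the four-column exchange
#' table, risk curves as (threshold, empirical_risk, adjusted_risk), label
#' tables as (sample_id, true_labels), and cross-validation results as one row
#' per run.
#'
#' @param x object to render.
#' @param ... further arguments (`labelSep` for set-valued cells).
#' @return a data.frame.
#' @name asTable
NULL

#' @rdname asTable
#' @param labelSep separator for set-valued cells (default ";").
#' @export
setMethod("asTable", "PredictionSetTable", function(x, labelSep = ";") {
  data.frame(sample_id = x@sampleIds,
             prediction_set = vapply(x@sets, paste, character(1),
                                     collapse = labelSep),
             set_size = lengths(x@sets),
             size_category = x@sizeCategory)
})

#' @rdname asTable
#' @export
setMethod("asTable", "LabelTable", function(x, labelSep = ";") {
  data.frame(sample_id = x@sampleIds,
             true_labels = vapply(x@labels, function(l)
               if (length(l) == 0) "unknown" else paste(l, collapse = labelSep),
               character(1)))
})

#' @rdname asTable
#' @export
setMethod("asTable", "RiskCurve", function(x, ...) {
  data.frame(threshold = x@thresholds,
             empirical_risk = x@empiricalRisk,
             adjusted_risk = x@adjustedRisk)
})

#' @rdname asTable
#' @export
setMethod("asTable", "CrossValResult", function(x, ...) {
  data.frame(run = seq_len(x@nRuns),
             fnr = x@runFnr,
             mean_set_size = x@runSetSize,
             prop_empty = x@runPropEmpty,
             prop_certain = x@runPropCertain,
             prop_uncertain = x@runPropUncertain)
})

#' @rdname asTable
#' @export
setMethod("asTable", "AlphaScan", function(x, ...) x@grid)

#' Export set compositions as an upset-style membership table
#'
#' One row per distinct prediction set observed in an evaluation, one logical
#' column per member class, plus the count of samples carrying exactly that
#' set — the numeric twin of an upset plot.
#'
#' @param report an [EvalReport-class].
#' @param classNames optional class universe ordering the columns; defaults to
#'   the classes observed in the sets.
#' @return data.frame of logical membership columns and a `count` column.
#' @export
upsetTable <- function(report, classNames = NULL) {
  stopifnot(is(report, "EvalReport"))
  comp <- report@setCompositions
  members <- strsplit(comp$set, ";", fixed = TRUE)
  if (is.null(classNames)) classNames <- sort(unique(unlist(members)))
  mem <- vapply(classNames, function(cl)
    vapply(members, function(s) cl %in% s, logical(1)),
    logical(nrow(comp)))
  mem <- matrix(mem, nrow = nrow(comp),
                dimnames = list(NULL, classNames))
  out <- data.frame(mem, check.names = FALSE)
  out$set_size <- lengths(members)
  out$count <- comp$count
  out
}

#' Serialize an evaluation report to structured text
#'
#' Writes the scalar summaries, per-class strata, set compositions and
#' co-occurrence fractions as YAML.
#'
#' @param report an [EvalReport-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeEvalReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  obj <- list(
    format_version = .MODEL_FORMAT_VERSION,
    overall_fnr_percent = if (is.na(report@overallFnr)) NULL else report@overallFnr,
    overall_fnr_percent_rounded = if (is.na(report@overallFnr)) NULL else
      round(report@overallFnr, 2),
    mean_set_size = report@meanSetSize,
    prop_empty = report@propEmpty,
    prop_certain = report@propCertain,
    prop_uncertain = report@propUncertain,
    n_samples = report@nSamples,
    n_labeled = report@nLabeled,
    n_multi_truth = report@nMultiTruth,
    multi_truth_fnr_percent = if (is.na(report@multiTruthFnr)) NULL else
      report@multiTruthFnr,
    loss_type = report@lossType,
    per_class = lapply(seq_len(nrow(report@perClass)), function(i)
      as.list(report@perClass[i, ])),
    set_compositions = lapply(seq_len(nrow(report@setCompositions)), function(i)
      as.list(report@setCompositions[i, ])),
    cooccurrence = as.list(report@cooccurrence))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Serialize a cross-validation result to structured text
#'
#' Writes the aggregates (means and Monte-Carlo standard errors) and the
#' per-class pooled summary as YAML; per-run values are exported separately
#' through [asTable()].
#'
#' @param x a [CrossValResult-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeCrossValResult <- function(x, path) {
  stopifnot(is(x, "CrossValResult"))
  obj <- list(
    format_version = .MODEL_FORMAT_VERSION,
    alpha = x@alpha, n_runs = x@nRuns, cal_fraction = x@calFraction,
    seed = x@seed,
    mean_fnr_percent = x@meanFnr, se_fnr_percent = x@seFnr,
    mean_set_size = x@meanSetSize, se_set_size = x@seSetSize,
    mean_prop_empty = mean(x@runPropEmpty),
    mean_prop_certain = mean(x@runPropCertain),
    mean_prop_uncertain = mean(x@runPropUncertain),
    per_class = lapply(seq_len(nrow(x@perClass)), function(i)
      as.list(x@perClass[i, ])))
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Write and read a simulation spec as a structured text config
#'
#' @param spec a [SimulationSpec-class].
#' @param path destination file.
#' @return `path` (write) or a validated [SimulationSpec-class] (read).
#' @export
writeSimulationSpec <- function(spec, path) {
  stopifnot(is(spec, "SimulationSpec"))
  obj <- list(format_version = .MODEL_FORMAT_VERSION,
              class_names = as.list(spec@classNames),
              class_frequencies = as.list(spec@classFrequencies),
              confusion_weights = lapply(seq_len(nrow(spec@confusionWeights)),
                                         function(i) as.list(spec@confusionWeights[i, ])),
              on_target_shape = as.list(spec@onTargetShape),
              off_target_shape = as.list(spec@offTargetShape),
              confused_shape = as.list(spec@confusedShape),
              multi_truth_fraction = spec@multiTruthFraction,
              ood_fraction = spec@oodFraction,
              n_samples = spec@nSamples,
              seed = spec@seed)
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname writeSimulationSpec
#' @export
readSimulationSpec <- function(path) {
  if (!file.exists(path)) .stopValidation("spec file not found: %s", path)
  obj <- yaml::read_yaml(path)
  need <- c("class_names", "class_frequencies", "confusion_weights",
            "on_target_shape", "off_target_shape", "confused_shape",
            "multi_truth_fraction", "ood_fraction", "n_samples", "seed")
  missing <- setdiff(need, names(obj))
  if (length(missing) > 0)
    .stopValidation("spec file %s is missing fields: %s", path,
                    paste(missing, collapse = ", "))
  K <- length(obj$class_names)
  w <- do.call(rbind, lapply(obj$confusion_weights, unlist))
  dimnames(w) <- list(unlist(obj$class_names), unlist(obj$class_names))
  simulationSpec(classNames = unlist(obj$class_names),
                 classFrequencies = unlist(obj$class_frequencies),
                 confusionWeights = w,
                 onTargetShape = unlist(obj$on_target_shape),
                 offTargetShape = unlist(obj$off_target_shape),
                 confusedShape = unlist(obj$confused_shape),
                 multiTruthFraction = obj$multi_truth_fraction,
                 oodFraction = obj$ood_fraction,
                 nSamples = obj$n_samples,
                 seed = obj$seed)
}
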