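#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Performance evaluation. The central routine is leave-one-out
## cross-validation with feature selection *inside* every fold (the
## leakage-free protocol): the held-out sample is removed before
## standardisation and before any feature ranking. Selecting features on
## all samples first and cross-validating afterwards (provided as
## loocvCV1() for contrast) is biased and over-optimistic.
## ---------------------------------------------------------------------------

.toFreqMatrix <- function(x) {
  stopifnot(is(x, "KTupleExperiment"))
  if (matrixState(x) == "counts") x <- toFrequencies(x)
  if (matrixState(x) != "frequencies")
    stop("expected a counts- or frequencies-state KTupleExperiment")
  x
}

.labelsPlusMinus <- function(x, labels = NULL) {
  if (is.null(labels)) labels <- sampleLabels(x)
  if (any(is.na(labels))) stop("all samples must be labelled")
  if (!all(labels %in% c(1L, 2L))) stop("labels must be 1 or 2")
  # class 1 maps to +1, class 2 to -1
  ifelse(as.integer(labels) == 1L, 1L, -1L)
}

## one CV2 fold given the frequency assay matrix M (features x samples):
## returns per-level predictions and selected features (in original 4^k
## column indices)
.cv2Fold <- function(M, y, i, levels, cost, scope, globalZ = NULL,
                     globalKeep = NULL) {
  if (scope == "train_only") {
    Mtr <- M[, -i, drop = FALSE]
    std <- .fitStdF(Mtr)
    Ztr <- t(.applyStdF(Mtr, std))
    zte <- t(.applyStdF(M[, i, drop = FALSE], std))
    keepIdx <- which(std$keep)
  } else {
    Ztr <- globalZ[-i, , drop = FALSE]
    zte <- globalZ[i, , drop = FALSE]
    keepIdx <- globalKeep
  }
  pFold <- ncol(Ztr)
  # a level above the fold's available (non-constant) feature count simply
  # uses all available features; duplicates collapse into one trained model
  foldLadder <- unique(pmin(levels, pFold))
  rs <- .recursiveSelectCore(Ztr, y[-i], foldLadder, cost)
  pred <- vapply(seq_along(levels), function(j) {
    jj <- match(min(levels[j], pFold), foldLadder)
    feat <- rs$features[[jj]]
    m <- rs$models[[jj]]
    f <- drop(zte[, feat, drop = FALSE] %*% m@weights) + m@bias
    if (f >= 0) 1L else -1L
  }, 1L)
  list(pred = pred,
       features = lapply(rs$features, function(f) keepIdx[f]))
}

#' Leave-one-out cross-validation with embedded feature selection (CV2)
#'
#' For every fold, one sample is held out; the standardizer is fit and the
#' recursive SVM selection is run on the remaining samples only; the
#' held-out sample is then predicted at every ladder level. After all
#' samples have been left out once, the per-level error rate is the
#' fraction of misclassified held-out samples.
#'
#' @param x a \linkS4class{KTupleExperiment} (counts or frequencies) with
#'   binary labels (1/2) in \code{colData}, at least 2 samples per class.
#' @param baseLevels descending base ladder below the all-features level
#'   (default [defaultLadder()]).
#' @param cost soft-margin penalty C.
#' @param scope \code{"train_only"} (default) refits standardisation
#'   inside each fold, keeping the protocol leakage-free; \code{"global"}
#'   standardises once across all samples before cross-validating.
#' @param labels optional label override (1/2 per sample), used by the
#'   permutation test.
#' @return A \linkS4class{CV2Result}.
#' @seealso [bestResult()], [finalModel()], [permutationTest()]
#' @export
loocvCV2 <- function(x, baseLevels = defaultLadder(), cost = 1,
                     scope = c("train_only", "global"), labels = NULL) {
  scope <- match.arg(scope)
  x <- .toFreqMatrix(x)
  y <- .labelsPlusMinus(x, labels)
  if (sum(y == 1L) < 2L || sum(y == -1L) < 2L)
    stop("each class needs at least 2 samples for LOOCV")
  M <- SummarizedExperiment::assay(x, "ktuple")
  n <- ncol(M)
  levels <- buildLadder(nrow(M), baseLevels)
  globalZ <- globalKeep <- NULL
  if (scope == "global") {
    std <- .fitStdF(M)
    globalZ <- t(.applyStdF(M, std))
    globalKeep <- which(std$keep)
  }
  preds <- matrix(NA_integer_, n, length(levels),
                  dimnames = list(colnames(M), levels))
  foldFeatures <- vector("list", n)
  for (i in seq_len(n)) {
    fold <- .cv2Fold(M, y, i, levels, cost, scope, globalZ, globalKeep)
    preds[i, ] <- fold$pred
    foldFeatures[[i]] <- fold$features
  }
  err <- colMeans(preds != y)
  methods::new("CV2Result", k = tupleLength(x), levels = levels,
               errorRates = unname(err), predictions = preds,
               foldFeatures = foldFeatures, nSamples = n, labels = y,
               scope = scope)
}

#' Biased LOOCV with feature selection outside the folds (CV1)
#'
#' The contrast protocol: features are selected once on \emph{all}
#' samples (global standardisation, recursive selection on the full data)
#' and only the SVM refit is cross-validated on the fixed subsets. Because
#' the held-out sample influenced the feature ranking, the resulting
#' accuracy is optimistically biased; this function exists to demonstrate
#' that bias, not for reporting performance.
#'
#' @inheritParams loocvCV2
#' @return A \linkS4class{CV2Result} with scope \code{"cv1_biased"}.
#' @export
loocvCV1 <- function(x, baseLevels = defaultLadder(), cost = 1,
                     labels = NULL) {
  x <- .toFreqMatrix(x)
  y <- .labelsPlusMinus(x, labels)
  Xf <- ktupleValues(x)
  n <- nrow(Xf)
  std <- .fitStd(Xf)
  Z <- .applyStd(Xf, std)
  keepIdx <- which(std$keep)
  ladder <- c(ncol(Z), baseLevels[baseLevels < ncol(Z)])
  levels <- buildLadder(ncol(Xf), baseLevels)
  rs <- .recursiveSelectCore(Z, y, ladder, cost)
  preds <- matrix(NA_integer_, n, length(levels))
  for (j in seq_along(ladder)) {
    tgt <- if (j == 1L) 1L else match(ladder[j], levels)
    feat <- rs$features[[j]]
    for (i in seq_len(n)) {
      m <- trainLinearSVM(Z[-i, feat, drop = FALSE], y[-i], cost = cost)
      preds[i, tgt] <- predict(m, Z[i, feat, drop = FALSE])
    }
  }
  err <- colMeans(preds != y)
  methods::new("CV2Result", k = tupleLength(x), levels = levels,
               errorRates = unname(err), predictions = preds,
               foldFeatures = list(lapply(rs$features,
                                          function(f) keepIdx[f])),
               nSamples = n, labels = y, scope = "cv1_biased")
}

#' Pick the best (k, level) result
#'
#' Applies the priority rule: restrict to selection levels at or below
#' \code{maxLevel} (the cap is inclusive; when no level qualifies, all are
#' considered), then pick the highest accuracy, breaking ties by the
#' smaller selection level and then the shorter tuple length. Levels with
#' undefined accuracy are ignored.
#'
#' @param results a \linkS4class{CV2Result} or a list of them (one per k).
#' @param maxLevel level cap (default 200).
#' @return A \linkS4class{BestResult}.
#' @export
bestResult <- function(results, maxLevel = 200L) {
  if (is(results, "CV2Result")) results <- list(results)
  if (length(results) == 0L) stop("no results supplied")
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(k = r@k, level = r@levels, accuracy = 1 - r@errorRates)
  }))
  df <- df[!is.na(df$accuracy), , drop = FALSE]
  if (nrow(df) == 0L) stop("no defined accuracies to choose from")
  elig <- df[df$level <= maxLevel, , drop = FALSE]
  if (nrow(elig) == 0L) elig <- df
  elig <- elig[order(-elig$accuracy, elig$level, elig$k), , drop = FALSE]
  rownames(elig) <- NULL
  methods::new("BestResult", k = as.integer(elig$k[1]),
               level = as.integer(elig$level[1]),
               accuracy = elig$accuracy[1], trace = elig)
}

#' Fit the final all-samples classifier
#'
#' After cross-validation has identified a working (k, level), the
#' recursive selection is rerun on \emph{all} samples to obtain one
#' definitive feature set and one model: the standardizer is fit on all
#' samples, the full ladder is descended, and the model at the requested
#' level is packaged with its selected words and standardisation
#' parameters for use on new samples.
#'
#' @param x a \linkS4class{KTupleExperiment} (counts or frequencies) with
#'   labels.
#' @param level the selection level to extract; must lie on the ladder.
#' @param baseLevels base ladder (default [defaultLadder()]).
#' @param cost soft-margin penalty C.
#' @param labels optional label override.
#' @return A \linkS4class{KTupleClassifier}.
#' @seealso [predictSamples()], [writeModelJSON()]
#' @export
finalModel <- function(x, level, baseLevels = defaultLadder(), cost = 1,
                       labels = NULL) {
  x <- .toFreqMatrix(x)
  y <- .labelsPlusMinus(x, labels)
  Xf <- ktupleValues(x)
  std <- .fitStd(Xf)
  Z <- .applyStd(Xf, std)
  keepIdx <- which(std$keep)
  ladder <- c(ncol(Z), baseLevels[baseLevels < ncol(Z)])
  level <- as.integer(level)
  j <- match(level, ladder)
  if (is.na(j)) {
    if (level == ncol(Xf)) j <- 1L
    else stop("level ", level, " is not on the ladder (",
              paste(ladder, collapse = ", "), ")")
  }
  rs <- .recursiveSelectCore(Z, y, ladder, cost)
  feat <- rs$features[[j]]
  orig <- keepIdx[feat]
  m <- rs$models[[j]]
  methods::new("KTupleClassifier", k = tupleLength(x),
               level = as.integer(ladder[j]),
               words = featureWords(x)[orig],
               mean = unname(std$mean[orig]), sd = unname(std$sd[orig]),
               weights = m@weights, bias = m@bias, cost = cost)
}

#' Classify new samples with a fitted k-tuple classifier
#'
#' Counts the classifier's k-tuple words in each new sample, normalises by
#' the sample's total window count, applies the stored standardisation and
#' the linear decision function. When true labels are available, accuracy,
#' sensitivity and specificity (class 1 = positive) are attached.
#'
#' @param classifier a \linkS4class{KTupleClassifier}.
#' @param samples list of \linkS4class{ReadSet}, or a
#'   \linkS4class{KTupleExperiment} in the counts state with matching k.
#' @return data.frame with columns \code{sample_id}, \code{decision},
#'   \code{predicted} (1/2) and, when labels are present, \code{label};
#'   performance measures are in \code{attr(, "performance")}.
#' @export
predictSamples <- function(classifier, samples) {
  stopifnot(is(classifier, "KTupleClassifier"))
  if (is(samples, "ReadSet")) samples <- list(samples)
  if (is.list(samples) && length(samples) == 0L)
    return(data.frame(sample_id = character(), decision = numeric(),
                      predicted = integer()))
  kte <- if (is(samples, "KTupleExperiment")) samples
         else buildCountMatrix(samples, tupleLength(classifier))
  if (tupleLength(kte) != tupleLength(classifier))
    stop("sample matrix was counted with k = ", tupleLength(kte),
         " but the classifier uses k = ", tupleLength(classifier))
  kte <- .toFreqMatrix(kte)
  Xf <- ktupleValues(kte)[, classifier@words, drop = FALSE]
  z <- (Xf - rep(classifier@mean, each = nrow(Xf))) /
    rep(classifier@sd, each = nrow(Xf))
  f <- drop(z %*% classifier@weights) + classifier@bias
  out <- data.frame(sample_id = colnames(kte), decision = f,
                    predicted = ifelse(f >= 0, 1L, 2L))
  lab <- sampleLabels(kte)
  if (!all(is.na(lab))) {
    out$label <- lab
    tp <- sum(out$predicted == 1L & lab == 1L)
    tn <- sum(out$predicted == 2L & lab == 2L)
    attr(out, "performance") <- c(
      accuracy = mean(out$predicted == lab),
      sensitivity = if (any(lab == 1L)) tp / sum(lab == 1L) else NA_real_,
      specificity = if (any(lab == 2L)) tn / sum(lab == 2L) else NA_real_)
  }
  out
}

## per-level sensitivity/specificity from a CV2Result (class 1 = positive)
.cvPerformance <- function(r) {
  y <- r@labels
  t(apply(r@predictions, 2L, function(p) {
    c(sensitivity = mean(p[y == 1L] == 1L),
      specificity = mean(p[y == -1L] == -1L))
  }))
}

#' Tabulate CV2 results
#'
#' Flattens one or more \linkS4class{CV2Result} objects into a data.frame
#' with per-(k, level) error rate, accuracy, sensitivity and specificity.
#'
#' @param results a \linkS4class{CV2Result} or list of them.
#' @return A data.frame.
#' @export
cvResultsTable <- function(results) {
  if (is(results, "CV2Result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    perf <- .cvPerformance(r)
    data.frame(k = r@k, level = r@levels, error_rate = r@errorRates,
               accuracy = 1 - r@errorRates,
               sensitivity = perf[, "sensitivity"],
               specificity = perf[, "specificity"],
               row.names = NULL)
  }))
}

#' Serialize / restore a k-tuple classifier as JSON
#'
#' The JSON carries everything needed to classify new samples without
#' retraining: k, the selected words, their standardisation parameters,
#' the weights, bias and cost.
#'
#' @param classifier a \linkS4class{KTupleClassifier}.
#' @param path output (input) file path.
#' @return \code{writeModelJSON}: the path, invisibly.
#' @export
writeModelJSON <- function(classifier, path) {
  stopifnot(is(classifier, "KTupleClassifier"))
  jsonlite::write_json(list(
    format = "metaRSVM-classifier", version = 1L,
    k = classifier@k, level = classifier@level, words = classifier@words,
    mean = classifier@mean, sd = classifier@sd,
    weights = classifier@weights, bias = classifier@bias,
    cost = classifier@cost), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJSON
#' @return \code{readModelJSON}: the restored
#'   \linkS4class{KTupleClassifier}.
#' @export
readModelJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "metaRSVM-classifier"))
    stop(path, " is not a serialized metaRSVM classifier")
  methods::new("KTupleClassifier", k = as.integer(j$k),
               level = as.integer(j$level), words = as.character(j$words),
               mean = as.numeric(j$mean), sd = as.numeric(j$sd),
               weights = as.numeric(j$weights), bias = as.numeric(j$bias),
               cost = as.numeric(j$cost))
}
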