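#' @include AllClasses.R
NULL

#' Accessors for metaRSVM classes
#'
#' Small accessor generics: slot access is never part of the public
#' interface.
#'
#' @param object an object of the documented classes.
#' @return The corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("reads", function(object) standardGeneric("reads"))

#' @rdname accessors
#' @export
setGeneric("sampleLabel", function(object) standardGeneric("sampleLabel"))

#' @rdname accessors
#' @export
setGeneric("tupleLength", function(object) standardGeneric("tupleLength"))

#' @rdname accessors
#' @export
setGeneric("matrixState", function(object) standardGeneric("matrixState"))

#' @rdname accessors
#' @export
setGeneric("featureWords", function(object) standardGeneric("featureWords"))

#' @rdname accessors
#' @export
setGeneric("ktupleValues", function(object) standardGeneric("ktupleValues"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("svmWeights", function(object) standardGeneric("svmWeights"))

#' @rdname accessors
#' @export
setGeneric("svmBias", function(object) standardGeneric("svmBias"))

#' @rdname accessors
#' @export
setGeneric("dualCoefs", function(object) standardGeneric("dualCoefs"))

#' @rdname accessors
#' @export
setGeneric("featureSubset", function(object) standardGeneric("featureSubset"))

#' @rdname accessors
#' @export
setGeneric("ladderLevels", function(object) standardGeneric("ladderLevels"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures",
           function(object, ...) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("errorRates", function(object) standardGeneric("errorRates"))

#' @rdname accessors
#' @export
setGeneric("accuracies", function(object) standardGeneric("accuracies"))

#' @rdname accessors
#' @export
setGeneric("nullAccuracies", function(object) standardGeneric("nullAccuracies"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

## ---- ReadSet ----

#' @rdname accessors
setMethod("sampleId", "ReadSet", function(object) object@sampleId)

#' @rdname accessors
setMethod("reads", "ReadSet", function(object) object@reads)

#' @rdname accessors
setMethod("sampleLabel", "ReadSet", function(object) object@label)

setMethod("show", "ReadSet", function(object) {
  cat("ReadSet", object@sampleId,
      sprintf("| %d reads | label: %s\n", length(object@reads),
              ifelse(is.na(object@label), "none", object@label)))
})

## ---- KTupleExperiment ----

#' @rdname accessors
setMethod("tupleLength", "KTupleExperiment",
          function(object) S4Vectors::metadata(object)$k)

#' @rdname accessors
setMethod("matrixState", "KTupleExperiment",
          function(object) S4Vectors::metadata(object)$state)

#' @rdname accessors
setMethod("featureWords", "KTupleExperiment", function(object) rownames(object))

#' @rdname accessors
#' @details \code{ktupleValues()} returns the samples-by-features
#'   orientation (samples in rows), the natural orientation for the
#'   classifier; the underlying assay stores features in rows per
#'   SummarizedExperiment convention.
setMethod("ktupleValues", "KTupleExperiment",
          function(object) t(SummarizedExperiment::assay(object, "ktuple")))

#' @rdname accessors
setMethod("sampleLabels", "KTupleExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  if ("label" %in% colnames(cd)) as.integer(cd$label)
  else rep(NA_integer_, ncol(object))
})

setMethod("show", "KTupleExperiment", function(object) {
  cat(sprintf("KTupleExperiment | k = %d | state = %s | %d features x %d samples\n",
              tupleLength(object), matrixState(object),
              nrow(object), ncol(object)))
  lab <- sampleLabels(object)
  if (!all(is.na(lab)))
    cat(sprintf("labels: %d in class 1, %d in class 2\n",
                sum(lab == 1L, na.rm = TRUE), sum(lab == 2L, na.rm = TRUE)))
})

## ---- LinearSVMModel ----

#' @rdname accessors
setMethod("svmWeights", "LinearSVMModel", function(object) object@weights)

#' @rdname accessors
setMethod("svmBias", "LinearSVMModel", function(object) object@bias)

#' @rdname accessors
setMethod("dualCoefs", "LinearSVMModel", function(object) object@alpha)

#' @rdname accessors
setMethod("featureSubset", "LinearSVMModel", function(object) object@featureSubset)

setMethod("show", "LinearSVMModel", function(object) {
  cat(sprintf("LinearSVMModel | %d features | %d support vectors | C = %g\n",
              length(object@weights), length(object@alpha), object@cost))
})

## ---- RecursiveSelection ----

#' @rdname accessors
setMethod("ladderLevels", "RecursiveSelection", function(object) object@levels)

#' @rdname accessors
#' @param level a ladder level present in the object (defaults to the
#'   bottom level).
#' @param ... passed on between methods.
setMethod("selectedFeatures", "RecursiveSelection",
          function(object, level = NULL, ...) {
  if (is.null(level)) level <- object@levels[length(object@levels)]
  j <- match(level, object@levels)
  if (is.na(j)) stop("level ", level, " is not on the ladder")
  object@features[[j]]
})

setMethod("show", "RecursiveSelection", function(object) {
  cat("RecursiveSelection | ladder:",
      paste(object@levels, collapse = " > "), "\n")
})

## ---- CV2Result ----

#' @rdname accessors
setMethod("ladderLevels", "CV2Result", function(object) object@levels)

#' @rdname accessors
setMethod("errorRates", "CV2Result", function(object) {
  stats::setNames(object@errorRates, object@levels)
})

#' @rdname accessors
setMethod("accuracies", "CV2Result", function(object) {
  stats::setNames(1 - object@errorRates, object@levels)
})

#' @rdname accessors
setMethod("tupleLength", "CV2Result", function(object) object@k)

setMethod("show", "CV2Result", function(object) {
  cat(sprintf("CV2Result | k = %d | %d samples | scope = %s\n",
              object@k, object@nSamples, object@scope))
  print(round(errorRates(object), 3))
})

## ---- BestResult ----

setMethod("show", "BestResult", function(object) {
  cat(sprintf("BestResult | %d-tuple | %d features | accuracy %.2f\n",
              object@k, object@level, object@accuracy))
})

#' @rdname accessors
setMethod("tupleLength", "BestResult", function(object) object@k)

## ---- PermutationResult ----

#' @rdname accessors
setMethod("nullAccuracies", "PermutationResult",
          function(object) object@nullAccuracies)

#' @rdname accessors
setMethod("pValue", "PermutationResult", function(object) object@pValue)

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult | %d permutations | observed accuracy %.3f | p %s\n",
              object@nPerm, object@observed, object@pLabel))
})

## ---- KTupleClassifier ----

#' @rdname accessors
setMethod("tupleLength", "KTupleClassifier", function(object) object@k)

#' @rdname accessors
setMethod("featureWords", "KTupleClassifier", function(object) object@words)

#' @rdname accessors
setMethod("svmWeights", "KTupleClassifier", function(object) object@weights)

#' @rdname accessors
setMethod("svmBias", "KTupleClassifier", function(object) object@bias)

setMethod("show", "KTupleClassifier", function(object) {
  cat(sprintf("KTupleClassifier | k = %d | level %d | words: %s%s\n",
              object@k, object@level,
              paste(utils::head(object@words, 5), collapse = " "),
              if (length(object@words) > 5) " ..." else ""))
})
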