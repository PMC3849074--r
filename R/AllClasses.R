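#' @import methods
#' @importFrom Biostrings DNAStringSet
NULL

## Central S4 containers. KTupleExperiment extends SummarizedExperiment so
## the standard Bioconductor accessors (assay, colData, metadata) all work;
## k-tuple words live in the rownames, samples in the columns.

#' ReadSet: one sample's short reads
#'
#' Container for the reads of a single sample together with its identifier
#' and an optional binary class label. Reads are filtered on construction:
#' any read containing a character outside A/C/G/T (after uppercasing) is
#' discarded, following the rule that reads with ambiguity codes such as
#' \code{N} are dropped entirely rather than trimmed.
#'
#' @slot sampleId single character identifier, unique within a dataset.
#' @slot reads a \link[Biostrings]{DNAStringSet} of A/C/G/T-only reads.
#' @slot label integer class label, \code{1} or \code{2}, or \code{NA} for
#'   unlabelled samples.
#'
#' @seealso [filterReads()], [sampleReads()], [buildCountMatrix()]
#' @export
setClass("ReadSet",
  slots = c(sampleId = "character", reads = "DNAStringSet", label = "integer"))

setValidity("ReadSet", function(object) {
  msg <- NULL
  if (length(object@sampleId) != 1L || is.na(object@sampleId) ||
      !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (length(object@label) != 1L)
    msg <- c(msg, "label must be a single integer (or NA)")
  else if (!is.na(object@label) && !object@label %in% c(1L, 2L))
    msg <- c(msg, "label must be 1, 2 or NA")
  if (length(object@reads) > 0) {
    bad <- grepl("[^ACGT]", as.character(object@reads))
    if (any(bad))
      msg <- c(msg, "reads must contain only A/C/G/T (use filterReads())")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a ReadSet
#'
#' @param sampleId single character identifier.
#' @param reads character vector or \link[Biostrings]{DNAStringSet}.
#'   Reads containing characters outside A/C/G/T are removed (see
#'   [filterReads()]); surviving reads are uppercased.
#' @param label class label \code{1}, \code{2} or \code{NA}.
#'
#' @return A \linkS4class{ReadSet}.
#' @examples
#' rs <- ReadSet("s1", c("ACGT", "ACNGT", "acgt"), label = 1)
#' length(reads(rs))  # 2: the read with N was dropped
#' @export
ReadSet <- function(sampleId, reads, label = NA_integer_) {
  new("ReadSet",
      sampleId = as.character(sampleId),
      reads = DNAStringSet(filterReads(reads)),
      label = as.integer(label))
}

#' KTupleExperiment: samples-by-k-tuple feature matrix
#'
#' A \link[SummarizedExperiment]{SummarizedExperiment} holding one assay
#' named \code{"ktuple"} with the \eqn{4^k} DNA words of length \eqn{k} as
#' rows and samples as columns. The matrix is carried through three states:
#' \describe{
#'   \item{counts}{raw overlapping-window occurrence counts per sample;}
#'   \item{frequencies}{each sample's counts divided by its total number of
#'     counted windows, so each sample sums to 1 (depth normalisation);}
#'   \item{standardized}{per-feature z-scores, \eqn{(f - \mu)/\sigma}, with
#'     \eqn{\mu,\sigma} estimated on a designated set of fitting samples and
#'     constant features dropped.}
#' }
#' The state, the tuple length and (when standardized) the standardizer
#' parameters are stored in \code{metadata()}.
#'
#' @seealso [buildCountMatrix()], [toFrequencies()], [fitStandardizer()]
#' @export
setClass("KTupleExperiment", contains = "SummarizedExperiment")

setValidity("KTupleExperiment", function(object) {
  md <- S4Vectors::metadata(object)
  msg <- NULL
  if (is.null(md$k) || is.null(md$state))
    return("metadata must contain 'k' and 'state'")
  if (!md$state %in% c("counts", "frequencies", "standardized"))
    return("state must be one of counts/frequencies/standardized")
  m <- SummarizedExperiment::assay(object, "ktuple")
  if (md$state != "standardized" && nrow(m) != 4^md$k)
    msg <- c(msg, sprintf("expected %d rows for k=%d", 4^md$k, md$k))
  if (md$state == "counts") {
    if (any(m < 0) || any(abs(m - round(m)) > 1e-9))
      msg <- c(msg, "counts must be non-negative integers")
  } else if (md$state == "frequencies") {
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "frequency columns must each sum to 1")
  } else if (is.null(md$standardizer)) {
    msg <- c(msg, "standardized state requires standardizer metadata")
  }
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, "sample ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Trained two-class linear SVM decision function
#'
#' Stores the primal weight vector \eqn{w}, the bias \eqn{b}, the dual
#' coefficients \eqn{\alpha_i \ge 0} with their support-vector indices and
#' training labels, and the feature subset the model was trained on. The
#' decision function is \eqn{f(x) = w \cdot x + b} with
#' \eqn{w = \sum_i \alpha_i y_i x_i}; predicted label is
#' \eqn{\mathrm{sgn}(f(x))}, with \eqn{f(x)=0} mapped to \eqn{+1}.
#'
#' @slot weights numeric primal weight vector (one entry per model feature).
#' @slot bias numeric scalar.
#' @slot alpha non-negative dual coefficients of the support vectors.
#' @slot svIndex integer indices of the support vectors in the training set.
#' @slot labels integer training labels in \{-1, +1\}.
#' @slot featureSubset integer column indices (into the training matrix)
#'   the model was trained on.
#' @slot cost soft-margin penalty C.
#' @export
setClass("LinearSVMModel",
  slots = c(weights = "numeric", bias = "numeric", alpha = "numeric",
            svIndex = "integer", labels = "integer",
            featureSubset = "integer", cost = "numeric"))

setValidity("LinearSVMModel", function(object) {
  msg <- NULL
  if (any(object@alpha < -1e-8))
    msg <- c(msg, "dual coefficients must be non-negative")
  if (length(object@alpha) != length(object@svIndex))
    msg <- c(msg, "alpha and svIndex lengths differ")
  if (length(object@weights) != length(object@featureSubset))
    msg <- c(msg, "weights and featureSubset lengths differ")
  if (!all(object@labels %in% c(-1L, 1L)))
    msg <- c(msg, "labels must be -1/+1")
  if (is.null(msg)) TRUE else msg
})

#' Recursive feature-selection result
#'
#' Nested feature subsets and the per-level trained models produced by
#' [recursiveSelect()]. Subsets are nested down the ladder: the features at
#' level \eqn{j+1} are a subset of those at level \eqn{j}.
#'
#' @slot levels integer vector of ladder levels (feature counts), descending.
#' @slot features list of integer vectors: the original column indices kept
#'   at each level.
#' @slot models list of \linkS4class{LinearSVMModel}, one per level.
#' @slot scores list of numeric per-feature scores at each level.
#' @export
setClass("RecursiveSelection",
  slots = c(levels = "integer", features = "list", models = "list",
            scores = "list"))

setValidity("RecursiveSelection", function(object) {
  L <- length(object@levels)
  if (length(object@features) != L || length(object@models) != L)
    return("features/models must have one entry per level")
  for (j in seq_len(L)) {
    if (length(object@features[[j]]) != object@levels[j])
      return(sprintf("level %d holds %d features, expected %d",
                     j, length(object@features[[j]]), object@levels[j]))
    if (j > 1 && !all(object@features[[j]] %in% object@features[[j - 1]]))
      return("feature subsets must be nested down the ladder")
  }
  TRUE
})

#' Leave-one-out cross-validation (CV2) result
#'
#' Per-level LOOCV error rates under the leakage-free protocol in which the
#' held-out sample is removed before standardisation and feature selection.
#'
#' @slot k tuple length used.
#' @slot levels ladder levels (feature counts), descending; the first entry
#'   is the all-features level.
#' @slot errorRates per-level LOOCV error rate in [0, 1].
#' @slot predictions integer matrix (samples x levels) of held-out
#'   predictions in \{-1, +1\}.
#' @slot foldFeatures list (one per fold) of lists of selected feature
#'   indices per level, in the full 4^k column space.
#' @slot nSamples number of samples.
#' @slot labels true labels in \{-1, +1\} (class 1 is +1).
#' @slot scope standardisation scope used ("train_only" or "global").
#' @export
setClass("CV2Result",
  slots = c(k = "integer", levels = "integer", errorRates = "numeric",
            predictions = "matrix", foldFeatures = "list",
            nSamples = "integer", labels = "integer", scope = "character"))

setValidity("CV2Result", function(object) {
  msg <- NULL
  if (length(object@errorRates) != length(object@levels))
    msg <- c(msg, "one error rate per level required")
  if (any(object@errorRates < 0 | object@errorRates > 1, na.rm = TRUE))
    msg <- c(msg, "error rates must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Best-result selection
#'
#' The (k, level) pair picked by the priority rule: restrict to selection
#' levels at or below the level cap (200 by default), then highest accuracy,
#' then the smallest selection level, then the shortest tuple length.
#'
#' @slot k tuple length of the winning entry.
#' @slot level selection level (number of features).
#' @slot accuracy LOOCV accuracy in [0, 1].
#' @slot trace data.frame of all candidate (k, level, accuracy) rows in the
#'   priority order used for the decision.
#' @export
setClass("BestResult",
  slots = c(k = "integer", level = "integer", accuracy = "numeric",
            trace = "data.frame"))

#' Label-permutation test result
#'
#' @slot nPerm number of label permutations.
#' @slot nullAccuracies best LOOCV accuracy of each permuted dataset.
#' @slot observed best LOOCV accuracy on the true labels.
#' @slot pValue fraction of permutations with null accuracy >= observed.
#' @slot pLabel printable p-value; \code{"< 1/nPerm"} style bound when no
#'   permutation reaches the observed accuracy.
#' @export
setClass("PermutationResult",
  slots = c(nPerm = "integer", nullAccuracies = "numeric",
            observed = "numeric", pValue = "numeric", pLabel = "character"))

setValidity("PermutationResult", function(object) {
  if (length(object@nullAccuracies) != object@nPerm)
    return("need one null accuracy per permutation")
  TRUE
})

#' Serializable k-tuple classifier
#'
#' The final all-samples model at a chosen selection level, bundled with
#' everything needed to classify new samples: the selected k-tuple words,
#' their standardisation parameters and the linear decision function.
#'
#' @slot k tuple length.
#' @slot level selection level.
#' @slot words selected k-tuple words, in model feature order.
#' @slot mean,sd per-word standardisation parameters (fit on all training
#'   samples).
#' @slot weights,bias linear decision function on the standardized words.
#' @slot cost soft-margin penalty used in training.
#' @export
setClass("KTupleClassifier",
  slots = c(k = "integer", level = "integer", words = "character",
            mean = "numeric", sd = "numeric", weights = "numeric",
            bias = "numeric", cost = "numeric"))

setValidity("KTupleClassifier", function(object) {
  n <- length(object@words)
  if (length(object@mean) != n || length(object@sd) != n ||
      length(object@weights) != n)
    return("words, mean, sd and weights must have equal length")
  if (any(nchar(object@words) != object@k))
    return("every word must have length k")
  TRUE
})
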