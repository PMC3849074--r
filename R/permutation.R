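#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Label-permutation significance testing. Each permutation reruns the full
## CV2 pipeline (standardisation and feature selection refit inside every
## fold) on the same cached frequency matrices with shuffled labels; only
## the labels change, which is an exact optimisation because counting and
## depth normalisation are label-free.
## ---------------------------------------------------------------------------

#' Permute class labels
#'
#' Draws a uniform random permutation of the label vector; the multiset of
#' labels (the size of each class) is preserved by construction.
#'
#' @param y label vector.
#' @return A permuted copy of \code{y}.
#' @export
permuteLabels <- function(y) {
  y[sample.int(length(y))]
}

## p-value arithmetic shared by permutationTest and its tests: the count
## uses >= so the smallest attainable p is 1/nPerm; a zero count is
## reported as the bound "< 1/nPerm"
.permPValue <- function(nullAcc, observed) {
  nPerm <- length(nullAcc)
  count <- sum(nullAcc >= observed)
  list(pValue = count / nPerm,
       pLabel = if (count == 0) sprintf("< %s", format(1 / nPerm))
                else format(count / nPerm))
}

#' Label-permutation test of the best LOOCV accuracy
#'
#' Estimates the null distribution of the best cross-validated accuracy
#' when there is no association between features and labels: class labels
#' are randomly reassigned (class sizes preserved), the full CV2 pipeline
#' is rerun over the whole k grid, and the best accuracy (under the
#' [bestResult()] rule) is recorded for each permutation. The p-value is
#' the fraction of permutations whose best accuracy reaches or exceeds the
#' observed one; when no permutation reaches it, the p-value is reported
#' as the bound \code{"< 1/nPerm"}.
#'
#' @param kteList a \linkS4class{KTupleExperiment} or a list of them (one
#'   per tuple length k), all sharing samples and labels.
#' @param nPerm number of permutations (default 1000).
#' @param baseLevels,cost,scope passed to [loocvCV2()].
#' @param maxLevel level cap for [bestResult()].
#' @param observed optionally, a precomputed observed best accuracy; by
#'   default it is computed from the true labels.
#' @param seed optional integer seed for the permutation stream (kept
#'   separate from any simulation stream).
#' @return A \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(kteList, nPerm = 1000L,
                            baseLevels = defaultLadder(), cost = 1,
                            scope = "train_only", maxLevel = 200L,
                            observed = NULL, seed = NULL) {
  if (is(kteList, "KTupleExperiment")) kteList <- list(kteList)
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be at least 1")
  kteList <- lapply(kteList, .toFreqMatrix)
  y <- sampleLabels(kteList[[1]])
  if (any(is.na(y))) stop("all samples must be labelled")
  bestAcc <- function(labels) {
    cvs <- lapply(kteList, loocvCV2, baseLevels = baseLevels, cost = cost,
                  scope = scope, labels = labels)
    bestResult(cvs, maxLevel = maxLevel)@accuracy
  }
  if (is.null(observed)) observed <- bestAcc(y)
  run <- function() {
    vapply(seq_len(nPerm), function(b) bestAcc(permuteLabels(y)),
           numeric(1))
  }
  nullAcc <- if (is.null(seed)) run() else .withSeed(seed, run())
  p <- .permPValue(nullAcc, observed)
  methods::new("PermutationResult", nPerm = nPerm,
               nullAccuracies = nullAcc, observed = observed,
               pValue = p$pValue, pLabel = p$pLabel)
}
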