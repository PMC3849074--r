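#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Recursive SVM core. A linear soft-margin SVM is trained (libsvm via
## e1071); the per-feature contribution score is the SVM weight times the
## class-mean difference, s_j = w_j (m+_j - m-_j); recursion keeps the
## top-scoring features down a descending ladder of feature counts.
## ---------------------------------------------------------------------------

.BASE_LADDER <- c(1000L, 500L, 200L, 100L, 50L, 30L, 20L, 10L, 5L)

## exact n-column factor of the Gram matrix: B B' = x x'
.gramFactor <- function(x) {
  e <- eigen(tcrossprod(x), symmetric = TRUE)
  sweep(e$vectors, 2L, sqrt(pmax(e$values, 0)), "*")
}

#' The default selection ladder
#'
#' The descending feature-count ladder used below the all-features level:
#' 1000, 500, 200, 100, 50, 30, 20, 10, 5.
#'
#' @return Integer vector.
#' @export
defaultLadder <- function() .BASE_LADDER

#' Train a two-class linear SVM
#'
#' Fits a soft-margin linear-kernel SVM (libsvm through
#' \link[e1071]{svm}; deterministic for fixed input). The decision
#' function is oriented so that positive values predict class +1, and the
#' primal weights satisfy \eqn{w = \sum_i \alpha_i y_i x_i} over the
#' support vectors.
#'
#' @param x numeric matrix, samples in rows; typically standardized
#'   k-tuple frequencies.
#' @param y labels in \{-1, +1\}; both classes must be present.
#' @param cost soft-margin penalty C (default 1).
#' @param featureSubset integer indices recording which columns of the
#'   original feature space \code{x} is (bookkeeping only; defaults to
#'   \code{1:ncol(x)}).
#' @return A \linkS4class{LinearSVMModel}.
#' @examples
#' m <- trainLinearSVM(cbind(c(-1, 1)), c(-1, 1))
#' svmBias(m)          # symmetric problem: boundary at 0
#' predict(m, cbind(-0.5))
#' @export
trainLinearSVM <- function(x, y, cost = 1,
                           featureSubset = seq_len(ncol(x))) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be coded -1/+1")
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes")
  if (anyNA(x)) stop("training matrix contains missing values")
  # The linear-SVM dual depends on x only through the Gram matrix K = x x'.
  # For wide matrices (p > n) we train on an exact n-column factor B with
  # B B' = K: the dual solution (support vectors, coefficients, bias) is
  # identical, and the optimiser no longer touches the p-dimensional rows.
  xin <- if (ncol(x) > nrow(x)) .gramFactor(x) else x
  fit <- e1071::svm(xin, factor(y, levels = c(-1L, 1L)), kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = 1e-6)
  w <- drop(crossprod(fit$coefs, x[fit$index, , drop = FALSE]))
  b <- -fit$rho
  coefs <- drop(fit$coefs)
  # libsvm orients the decision function toward the class it saw first;
  # flip so positive f(x) always means class +1
  if (fit$levels[fit$labels[1]] == "-1") {
    w <- -w; b <- -b; coefs <- -coefs
  }
  alpha <- coefs * y[fit$index]
  methods::new("LinearSVMModel", weights = unname(w), bias = b,
               alpha = pmax(alpha, 0), svIndex = as.integer(fit$index),
               labels = y, featureSubset = as.integer(featureSubset),
               cost = cost)
}

#' Predict class labels with a linear SVM
#'
#' Returns \eqn{\mathrm{sgn}(w \cdot x + b)} per row; a decision value of
#' exactly zero maps to +1 (documented convention).
#'
#' @param object a \linkS4class{LinearSVMModel}.
#' @param newdata numeric matrix or vector restricted to the model's
#'   features (same number of columns as \code{svmWeights(object)}).
#' @param decision return raw decision values instead of labels.
#' @return Integer labels in \{-1, +1\}, or decision values.
#' @export
setMethod("predict", "LinearSVMModel",
          function(object, newdata, decision = FALSE) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object@weights))
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         length(object@weights))
  f <- drop(newdata %*% object@weights) + object@bias
  if (decision) f else ifelse(f >= 0, 1L, -1L)
})

#' R-SVM per-feature contribution scores
#'
#' Scores each feature by its class-mean difference weighted by the SVM
#' weight: \eqn{s_j = w_j (m^+_j - m^-_j)}, where \eqn{m^+_j} and
#' \eqn{m^-_j} are the means of feature j over the class +1 and class -1
#' training rows. Higher scores mean more discriminative features.
#'
#' @param model a \linkS4class{LinearSVMModel} trained on the columns of
#'   \code{x}.
#' @param x the training matrix (samples x model features).
#' @param y the training labels in \{-1, +1\}.
#' @return Numeric score per feature.
#' @export
featureScores <- function(model, x, y) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (ncol(x) != length(model@weights))
    stop("x does not match the model's feature space")
  if (!any(y == 1L) || !any(y == -1L))
    stop("both classes are needed to compute class means")
  mPlus <- colMeans(x[y == 1L, , drop = FALSE])
  mMinus <- colMeans(x[y == -1L, , drop = FALSE])
  unname(model@weights * (mPlus - mMinus))
}

#' Build the selection ladder for a feature space
#'
#' Starts from all available features and appends every base-ladder level
#' strictly smaller than the feature count, in descending order. For small
#' k the ladder is thereby truncated; e.g. 64 features (k = 3) give
#' \code{c(64, 50, 30, 20, 10, 5)}.
#'
#' @param nFeatures number of available features (>= 1).
#' @param base descending base levels (default [defaultLadder()]).
#' @return Strictly decreasing integer vector starting at
#'   \code{nFeatures}.
#' @examples
#' buildLadder(64)
#' buildLadder(4096)
#' buildLadder(5)
#' @export
buildLadder <- function(nFeatures, base = defaultLadder()) {
  nFeatures <- as.integer(nFeatures)
  if (nFeatures < 1) stop("nFeatures must be at least 1")
  base <- sort(unique(as.integer(base)), decreasing = TRUE)
  c(nFeatures, base[base < nFeatures])
}

## internal workhorse: minimal list output for the CV hot loop.
## Tie-breaking in the ranking: descending score, then descending |w|,
## then ascending column index -- fully deterministic.
.recursiveSelectCore <- function(x, y, ladder, cost = 1) {
  p <- ncol(x)
  if (ladder[1] > p) stop("ladder starts above the number of features")
  if (any(diff(ladder) >= 0)) stop("ladder must be strictly decreasing")
  L <- length(ladder)
  cur <- seq_len(p)
  features <- models <- scores <- vector("list", L)
  for (j in seq_len(L)) {
    if (length(cur) > ladder[j]) {
      # only reachable for j == 1 when ladder[1] < p: rank once to enter
      stop("internal: subset larger than ladder level")
    }
    xj <- x[, cur, drop = FALSE]
    model <- trainLinearSVM(xj, y, cost = cost, featureSubset = cur)
    s <- featureScores(model, xj, y)
    features[[j]] <- cur
    models[[j]] <- model
    scores[[j]] <- s
    if (j < L) {
      ord <- order(-s, -abs(model@weights), seq_along(cur))
      cur <- sort(cur[ord[seq_len(ladder[j + 1L])]])
    }
  }
  list(levels = as.integer(ladder), features = features, models = models,
       scores = scores)
}

#' Recursive feature selection down a ladder
#'
#' At each ladder level a linear SVM is trained on the surviving features,
#' features are scored with [featureScores()], and the top-scoring
#' \code{next level} features are kept for the next round. One model is
#' trained per level and used both for scoring and for prediction at that
#' level. Subsets are nested by construction.
#'
#' @param x numeric matrix (samples x features), typically standardized
#'   frequencies.
#' @param y labels in \{-1, +1\}.
#' @param ladder strictly decreasing levels with \code{ladder[1] ==
#'   ncol(x)}; default [buildLadder()] of the feature count.
#' @param cost soft-margin penalty C.
#' @return A \linkS4class{RecursiveSelection}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 20, 10)
#' y <- rep(c(-1, 1), each = 10)
#' x[y == 1, 1] <- x[y == 1, 1] + 4   # one planted feature
#' rs <- recursiveSelect(x, y, ladder = c(10L, 5L, 2L, 1L))
#' selectedFeatures(rs, 1)            # recovers column 1
#' @export
recursiveSelect <- function(x, y, ladder = buildLadder(ncol(x)), cost = 1) {
  x <- as.matrix(x)
  core <- .recursiveSelectCore(x, as.integer(y), as.integer(ladder), cost)
  methods::new("RecursiveSelection", levels = core$levels,
               features = core$features, models = core$models,
               scores = core$scores)
}
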