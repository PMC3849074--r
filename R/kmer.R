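#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## k-tuple feature extraction: overlapping-window word counts per sample,
## depth normalisation to relative frequencies, and per-feature z-scoring.
## Words are counted literally, with no reverse-complement collapsing:
## strand information enters through the data itself, since reads come from
## both strands, and a discriminative motif shows up both as itself and as
## its reverse complement.
## ---------------------------------------------------------------------------

.MAX_K <- 10L

.checkK <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 1) stop("k must be a positive integer")
  if (k > .MAX_K)
    stop("k > ", .MAX_K, " is not supported (dense 4^k feature space)")
  as.integer(k)
}

#' Remove reads containing ambiguous bases
#'
#' Reads are uppercased; any read containing a character outside A/C/G/T
#' (N or any other IUPAC ambiguity code) is removed entirely. Order is
#' preserved.
#'
#' @param reads character vector or \link[Biostrings]{XStringSet}.
#' @return Uppercase character vector of clean reads.
#' @examples
#' filterReads(c("ACGT", "ACNGT", "acgt"))
#' @export
filterReads <- function(reads) {
  reads <- toupper(as.character(reads))
  reads[!grepl("[^ACGT]", reads) & nzchar(reads)]
}

#' Count k-tuple occurrences across reads
#'
#' Scans every read with an overlapping window of width \code{k}: a read of
#' length L contributes \code{max(0, L - k + 1)} windows, and the counts of
#' all reads are summed into one vector over the \eqn{4^k} words in
#' lexicographic order (A < C < G < T). Reads shorter than \code{k}
#' contribute nothing.
#'
#' @param reads character vector or DNAStringSet of A/C/G/T reads (see
#'   [filterReads()]).
#' @param k tuple length (1 to 10).
#' @return Named numeric vector of length \eqn{4^k}.
#' @examples
#' v <- countKTuples("ACGTA", 2)
#' v[v > 0]
#' @export
countKTuples <- function(reads, k) {
  k <- .checkK(k)
  if (!methods::is(reads, "DNAStringSet"))
    reads <- Biostrings::DNAStringSet(as.character(reads))
  if (length(reads) == 0L)
    return(stats::setNames(numeric(4^k), Biostrings::mkAllStrings(.DNA, k)))
  as.numeric(Biostrings::oligonucleotideFrequency(
    reads, width = k, simplify.as = "collapsed")) |>
    stats::setNames(Biostrings::mkAllStrings(.DNA, k))
}

#' Build the samples-by-k-tuple count matrix
#'
#' Applies [countKTuples()] to every sample and assembles the counts into a
#' \linkS4class{KTupleExperiment} in the \code{"counts"} state, with
#' sample labels (when present) in \code{colData}.
#'
#' @param samples list of \linkS4class{ReadSet} with unique sample ids.
#' @param k tuple length.
#' @return A \linkS4class{KTupleExperiment}, state \code{"counts"}.
#' @examples
#' rs <- list(ReadSet("a", "ACGTACGT", 1), ReadSet("b", "TTTTTTTT", 2))
#' kte <- buildCountMatrix(rs, k = 2)
#' dim(kte)
#' @export
buildCountMatrix <- function(samples, k) {
  k <- .checkK(k)
  if (is(samples, "ReadSet")) samples <- list(samples)
  ids <- vapply(samples, sampleId, "")
  if (anyDuplicated(ids))
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  counts <- vapply(samples, function(rs) countKTuples(reads(rs), k),
                   numeric(4^k))
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(samples))
  rownames(counts) <- Biostrings::mkAllStrings(.DNA, k)
  colnames(counts) <- ids
  empty <- colSums(counts) == 0
  if (any(empty))
    stop("sample(s) with no countable k-tuple windows: ",
         paste(ids[empty], collapse = ", "))
  labels <- vapply(samples, sampleLabel, 1L)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ktuple = counts),
    colData = S4Vectors::DataFrame(sample_id = ids, label = labels,
                                   row.names = ids),
    metadata = list(k = k, state = "counts"))
  methods::new("KTupleExperiment", se)
}

#' Normalise counts to per-sample frequencies
#'
#' Divides each sample's counts by its own total so samples of different
#' sequencing depth become comparable; each sample's frequencies sum to 1.
#'
#' @param x a \linkS4class{KTupleExperiment} in the \code{"counts"} state.
#' @return The experiment in the \code{"frequencies"} state.
#' @export
toFrequencies <- function(x) {
  stopifnot(is(x, "KTupleExperiment"))
  if (matrixState(x) == "frequencies") return(x)
  if (matrixState(x) != "counts")
    stop("toFrequencies() expects a counts-state KTupleExperiment")
  m <- SummarizedExperiment::assay(x, "ktuple")
  tot <- colSums(m)
  if (any(tot <= 0)) stop("zero-count sample: ",
                          paste(colnames(m)[tot <= 0], collapse = ", "))
  SummarizedExperiment::assay(x, "ktuple") <- sweep(m, 2L, tot, "/")
  md <- S4Vectors::metadata(x)
  md$state <- "frequencies"
  S4Vectors::metadata(x) <- md
  methods::validObject(x)
  x
}

## internal standardizer: population (divide-by-n) standard deviation so
## that the fitted samples have variance exactly 1; zero-sd features are
## flagged constant and dropped. The *F variants work in the
## features-by-samples orientation (the assay layout), where centering and
## scaling are plain vector-recycled operations -- the hot path of the CV
## loop.
.fitStdF <- function(m) {
  mu <- rowMeans(m)
  ctr <- m - mu
  sd <- sqrt(rowMeans(ctr * ctr))
  list(mean = mu, sd = sd, keep = sd > 0)
}

.applyStdF <- function(m, std) {
  (m[std$keep, , drop = FALSE] - std$mean[std$keep]) / std$sd[std$keep]
}

## samples-by-features wrappers used by the public standardizer API
.fitStd <- function(m) .fitStdF(t(m))

.applyStd <- function(m, std) t(.applyStdF(t(m), std))

#' Fit per-feature standardisation parameters
#'
#' Computes, for every k-tuple word, the mean and population (divide-by-n)
#' standard deviation of its frequency over a designated set of fitting
#' samples. Features constant on the fitting samples are flagged and will
#' be dropped by [applyStandardizer()] (their z-score is undefined).
#'
#' @param x a \linkS4class{KTupleExperiment} in the \code{"frequencies"}
#'   state.
#' @param fitSamples indices (or names) of the samples used for fitting; at
#'   least 2. Defaults to all samples.
#' @return A list of class \code{"KTupleStandardizer"}: \code{mean},
#'   \code{sd}, \code{keep} (logical, FALSE = constant), \code{words},
#'   \code{k}, \code{fitSamples}.
#' @export
fitStandardizer <- function(x, fitSamples = seq_len(ncol(x))) {
  stopifnot(is(x, "KTupleExperiment"))
  if (matrixState(x) != "frequencies")
    stop("standardizer must be fit on frequencies")
  if (is.character(fitSamples)) fitSamples <- match(fitSamples, colnames(x))
  if (length(fitSamples) < 2L)
    stop("need at least 2 samples to fit a standardizer")
  m <- ktupleValues(x)[fitSamples, , drop = FALSE]
  std <- .fitStd(m)
  structure(c(std, list(words = featureWords(x), k = tupleLength(x),
                        fitSamples = fitSamples)),
            class = "KTupleStandardizer")
}

#' Apply a standardizer to a frequency matrix
#'
#' Transforms every sample's frequencies to z-scores using the fitted
#' parameters; features flagged constant during fitting are dropped from
#' all samples. Samples outside the fitting set are standardized with the
#' fitted parameters (their columns need not have mean 0).
#'
#' @param x a \linkS4class{KTupleExperiment} in the \code{"frequencies"}
#'   state with the same k and word ordering as the standardizer.
#' @param std result of [fitStandardizer()].
#' @return The experiment in the \code{"standardized"} state (constant
#'   features removed).
#' @export
applyStandardizer <- function(x, std) {
  stopifnot(is(x, "KTupleExperiment"), inherits(std, "KTupleStandardizer"))
  if (matrixState(x) != "frequencies")
    stop("applyStandardizer() expects frequencies")
  if (tupleLength(x) != std$k ||
      !identical(featureWords(x), std$words))
    stop("standardizer was fit for a different feature space")
  z <- t(.applyStd(ktupleValues(x), std))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ktuple = z),
    colData = SummarizedExperiment::colData(x),
    metadata = list(k = std$k, state = "standardized",
                    standardizer = std))
  methods::new("KTupleExperiment", se)
}

#' Count k-tuples for a sheet of samples
#'
#' Convenience pipeline: load each sample's reads from disk, filter, count
#' and assemble the count matrix.
#'
#' @param sheet a sample sheet (see [readSampleSheet()]) or its path.
#' @param k tuple length.
#' @return A \linkS4class{KTupleExperiment}, state \code{"counts"}.
#' @export
countSampleSheet <- function(sheet, k) {
  buildCountMatrix(loadSamples(sheet), k)
}
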