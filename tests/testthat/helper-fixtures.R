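## Shared fixtures and independent oracles. Everything is generated in
## code; no data files.

DNA4 <- c("A", "C", "G", "T")

## all k-words in lexicographic order (A < C < G < T), built without the
## package's own word machinery
allWords <- function(k) {
  w <- ""
  for (i in seq_len(k)) w <- as.vector(t(outer(w, DNA4, paste0)))
  w
}

## brute-force k-tuple counter: enumerates every substring explicitly
bruteCount <- function(reads, k) {
  counts <- stats::setNames(numeric(4^k), allWords(k))
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(r, i, i + k - 1)
      counts[w] <- counts[w] + 1
    }
  }
  counts
}

## string reverse complement, independent of the package's revComp
rcOracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(s, function(x) {
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

## a small fully characterised two-class dataset for pipeline tests
tinySimConfig <- function(rngSeed = 42, nPerClass = 5, genomeLength = 600,
                          coverage = 3, readLength = 30, nSeeds2 = 2,
                          seedLength = 4, density = 0.03, nSeeds1 = 0) {
  designSimulation(nSeeds1, nSeeds2, seedLength = seedLength,
                   density = density, rngSeed = rngSeed,
                   nPerClass = nPerClass, genomeLength = genomeLength,
                   coverage = coverage, readLength = readLength)
}

## four trivially separable samples: the classes share no k-mers at all
disjointSamples <- function() {
  list(ReadSet("a1", rep("ACACACAC", 5), 1),
       ReadSet("a2", rep("ACACACAA", 5), 1),
       ReadSet("b1", rep("GTGTGTGT", 5), 2),
       ReadSet("b2", rep("GTGTGTGG", 5), 2))
}

## build a CV2Result holding a given error-rate vector (for best-result
## rule tests); predictions are filled consistently with the rates
fakeCV2 <- function(k, levels, err) {
  n <- 50L
  preds <- matrix(1L, n, length(levels))
  labels <- rep(c(1L, -1L), each = n / 2)
  new("CV2Result", k = as.integer(k), levels = as.integer(levels),
      errorRates = as.numeric(err), predictions = preds,
      foldFeatures = list(), nSamples = n, labels = labels,
      scope = "train_only")
}
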