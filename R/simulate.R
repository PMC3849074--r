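#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Two-class benchmark simulator: uniform random background genomes, k-tuple
## seed motifs inserted at a controlled density, and error-free short reads
## sampled uniformly from both strands. Read sampling is deliberately simple
## (uniform start positions with replacement, fair strand choice, no errors):
## with error-free sequencing this is exactly the sampling model needed.
## ---------------------------------------------------------------------------

.DNA <- c("A", "C", "G", "T")

#' Specify a seed motif and its insertion density
#'
#' A seed is a short DNA motif inserted into a background genome. Its
#' density is defined as \eqn{l \times \#seed / n}: seed length times the
#' number of insertions, divided by the genome length. The number of
#' insertion events for a genome of length \eqn{n} is therefore
#' \code{round(density * n / l)} (half away from zero).
#'
#' @param sequence DNA string over A/C/G/T.
#' @param density fraction of the genome covered by insertions of this
#'   seed, in (0, 1).
#' @return A list of class \code{"SeedSpec"}.
#' @examples
#' seedSpec("TGTTGA", density = 0.005)
#' @export
seedSpec <- function(sequence, density) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || !nzchar(sequence) ||
      grepl("[^ACGT]", sequence))
    stop("seed sequence must be a non-empty A/C/G/T string")
  density <- as.numeric(density)
  if (length(density) != 1L || is.na(density) || density <= 0 || density >= 1)
    stop("seed density must lie in (0, 1)")
  structure(list(sequence = sequence, density = density), class = "SeedSpec")
}

#' Draw a set of distinct random seed motifs
#'
#' @param n number of seed kinds.
#' @param length seed length l in bases.
#' @param density insertion density shared by all seeds.
#' @param exclude character vector of sequences the new seeds must avoid
#'   (used to keep the two classes' seed sets disjoint).
#' @return A list of \code{SeedSpec} (empty list when \code{n == 0}).
#' @export
randomSeedSpecs <- function(n, length, density, exclude = character()) {
  if (n == 0) return(list())
  seqs <- character(0)
  while (length(seqs) < n) {
    cand <- paste(sample(.DNA, length, replace = TRUE), collapse = "")
    if (!cand %in% c(seqs, exclude)) seqs <- c(seqs, cand)
  }
  lapply(seqs, seedSpec, density = density)
}

#' Simulation configuration
#'
#' Bundles the full design of a two-class simulated dataset. Defaults are
#' the benchmark conditions used throughout: 25 genomes per class of length
#' 10,000 with uniform base composition, sequenced as error-free 50 bp
#' reads at 10-fold coverage.
#'
#' @param nPerClass genomes per class.
#' @param genomeLength genome length n in bases.
#' @param baseProbs probabilities of A, C, G, T; must sum to 1.
#' @param seedsClass1,seedsClass2 lists of [seedSpec()] inserted into the
#'   genomes of class 1 and class 2 respectively.
#' @param readLength read length in bases.
#' @param coverage expected per-base sequencing depth; the number of reads
#'   per genome is \code{round(coverage * genomeLength / readLength)}.
#' @param rngSeed integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nPerClass = 25L, genomeLength = 10000L,
                             baseProbs = rep(0.25, 4),
                             seedsClass1 = list(), seedsClass2 = list(),
                             readLength = 50L, coverage = 10,
                             rngSeed = 1L) {
  if (nPerClass < 1) stop("nPerClass must be at least 1")
  if (abs(sum(baseProbs) - 1) > 1e-12 || any(baseProbs < 0))
    stop("baseProbs must be non-negative and sum to 1")
  if (genomeLength < readLength)
    stop("genomeLength must be at least readLength")
  if (coverage <= 0) stop("coverage must be positive")
  for (s in c(seedsClass1, seedsClass2)) {
    if (!inherits(s, "SeedSpec")) stop("seeds must be built with seedSpec()")
    l <- nchar(s$sequence)
    if (s$density * genomeLength / l < 0.5)
      stop("seed '", s$sequence, "': density too low for even one insertion")
  }
  structure(list(nPerClass = as.integer(nPerClass),
                 genomeLength = as.integer(genomeLength),
                 baseProbs = as.numeric(baseProbs),
                 seedsClass1 = seedsClass1, seedsClass2 = seedsClass2,
                 readLength = as.integer(readLength),
                 coverage = as.numeric(coverage),
                 rngSeed = as.integer(rngSeed)),
            class = "SimulationConfig")
}

#' Build a simulation design with randomly drawn seed sets
#'
#' Convenience wrapper covering the standard benchmark designs: class 1
#' receives \code{nSeeds1} seed kinds, class 2 \code{nSeeds2}, all of
#' length \code{seedLength} at a common \code{density}. Seed sequences are
#' drawn at random (distinct within and across classes) from a stream
#' derived from \code{rngSeed}; design 1 corresponds to
#' \code{nSeeds1 = 0} (pure background in class 1), design 2 to seeds in
#' both classes.
#'
#' @param nSeeds1,nSeeds2 number of seed kinds per class.
#' @param seedLength seed length l.
#' @param density per-seed insertion density.
#' @param rngSeed integer seed for both seed drawing and the dataset.
#' @param ... further arguments to [simulationConfig()].
#' @return A \code{"SimulationConfig"}.
#' @examples
#' cfg <- designSimulation(0, 5, seedLength = 6, density = 0.005, rngSeed = 7)
#' vapply(cfg$seedsClass2, `[[`, "", "sequence")
#' @export
designSimulation <- function(nSeeds1, nSeeds2, seedLength, density,
                             rngSeed = 1L, ...) {
  .withSeed(childSeed(rngSeed, "seeds"), {
    s1 <- randomSeedSpecs(nSeeds1, seedLength, density)
    s2 <- randomSeedSpecs(nSeeds2, seedLength, density,
                          exclude = vapply(s1, `[[`, "", "sequence"))
    simulationConfig(seedsClass1 = s1, seedsClass2 = s2,
                     rngSeed = childSeed(rngSeed, "dataset"), ...)
  })
}

#' Generate a random background genome
#'
#' Draws \code{genomeLength} bases i.i.d. from \code{baseProbs}. Consumes
#' the global RNG stream; seed with \code{set.seed()} (or use
#' [generateDataset()], which manages seeding).
#'
#' @param genomeLength genome length in bases (> 0).
#' @param baseProbs probabilities of A, C, G, T summing to 1.
#' @return A single character string of length \code{genomeLength}.
#' @examples
#' set.seed(1)
#' g <- generateBackgroundGenome(100)
#' nchar(g)
#' @export
generateBackgroundGenome <- function(genomeLength, baseProbs = rep(0.25, 4)) {
  if (length(genomeLength) != 1L || is.na(genomeLength) || genomeLength < 1)
    stop("genomeLength must be a positive integer")
  if (length(baseProbs) != 4L || abs(sum(baseProbs) - 1) > 1e-12 ||
      any(baseProbs < 0))
    stop("baseProbs must be 4 non-negative probabilities summing to 1")
  paste(sample(.DNA, genomeLength, replace = TRUE, prob = baseProbs),
        collapse = "")
}

#' Insert seed motifs into a genome
#'
#' For each seed, \code{round(density * n / l)} insertion events are
#' performed (half away from zero). Each event picks a position uniformly
#' from \code{1..(n - l + 1)} and replaces the \code{l} bases starting
#' there with the seed, leaving the genome length unchanged. Positions are
#' drawn independently, so a later insertion may overwrite part of an
#' earlier one; the returned table records the insertion events, not the
#' surviving copies.
#'
#' @param genome character genome string.
#' @param seeds list of [seedSpec()].
#' @return A list with elements \code{genome} (the modified string) and
#'   \code{insertions} (data.frame with columns \code{seed},
#'   \code{position}).
#' @examples
#' set.seed(1)
#' out <- insertSeeds(strrep("A", 10), list(seedSpec("CGT", 0.3)))
#' out$insertions
#' @export
insertSeeds <- function(genome, seeds) {
  n <- nchar(genome)
  events <- list()
  for (s in seeds) {
    l <- nchar(s$sequence)
    if (l > n) stop("seed '", s$sequence, "' is longer than the genome")
    count <- .roundHalfAway(s$density * n / l)
    if (count < 1)
      stop("seed '", s$sequence, "': density gives no insertions")
    pos <- sample.int(n - l + 1L, count, replace = TRUE)
    for (p in pos) substr(genome, p, p + l - 1L) <- s$sequence
    events[[length(events) + 1L]] <-
      data.frame(seed = s$sequence, position = pos)
  }
  insertions <- if (length(events)) do.call(rbind, events)
                else data.frame(seed = character(), position = integer())
  list(genome = genome, insertions = insertions)
}

#' Sample error-free short reads from a genome
#'
#' Draws \code{round(coverage * n / readLength)} reads. Each read starts at
#' a position uniform on \code{1..(n - readLength + 1)} (with replacement)
#' and is taken from the forward or reverse strand with probability 1/2;
#' minus-strand reads are reverse-complemented. No sequencing errors are
#' introduced.
#'
#' @param genome character genome string.
#' @param readLength read length in bases (at most the genome length).
#' @param coverage expected fold coverage (> 0).
#' @param sampleId identifier for the resulting [ReadSet].
#' @param label optional class label (1, 2 or NA).
#' @return A \linkS4class{ReadSet}.
#' @examples
#' set.seed(1)
#' rs <- sampleReads(generateBackgroundGenome(1000), 50, 2, "s1")
#' length(reads(rs))  # round(2 * 1000 / 50) = 40
#' @export
sampleReads <- function(genome, readLength, coverage, sampleId = "sample",
                        label = NA_integer_) {
  n <- nchar(genome)
  if (readLength > n) stop("readLength exceeds the genome length")
  if (coverage <= 0) stop("coverage must be positive")
  nReads <- .roundHalfAway(coverage * n / readLength)
  starts <- sample.int(n - readLength + 1L, nReads, replace = TRUE)
  minus <- sample(c(FALSE, TRUE), nReads, replace = TRUE)
  rd <- substring(genome, starts, starts + readLength - 1L)
  if (any(minus)) rd[minus] <- revComp(rd[minus])
  ReadSet(sampleId, rd, label)
}

#' Generate a labelled two-class dataset
#'
#' Runs the full simulation for a [simulationConfig()]: per class,
#' \code{nPerClass} background genomes are generated, the class's seeds are
#' inserted, and reads are sampled. All randomness flows from
#' \code{config$rngSeed}; the same config yields an identical dataset.
#'
#' @param config a \code{"SimulationConfig"}.
#' @return A list of class \code{"SimulatedDataset"} with elements
#'   \code{samples} (list of labelled \linkS4class{ReadSet}), \code{truth}
#'   (data.frame of insertion events: \code{sample_id}, \code{label},
#'   \code{seed}, \code{position}) and \code{config}.
#' @examples
#' cfg <- designSimulation(0, 2, seedLength = 4, density = 0.01,
#'                         rngSeed = 3, nPerClass = 2, genomeLength = 500,
#'                         coverage = 2)
#' ds <- generateDataset(cfg)
#' length(ds$samples)
#' @export
generateDataset <- function(config) {
  if (!inherits(config, "SimulationConfig"))
    stop("config must be built with simulationConfig()")
  .withSeed(config$rngSeed, {
    samples <- vector("list", 2L * config$nPerClass)
    truth <- list()
    idx <- 0L
    for (cls in 1:2) {
      seeds <- if (cls == 1L) config$seedsClass1 else config$seedsClass2
      for (i in seq_len(config$nPerClass)) {
        idx <- idx + 1L
        id <- sprintf("class%d_s%02d", cls, i)
        g <- generateBackgroundGenome(config$genomeLength, config$baseProbs)
        ins <- insertSeeds(g, seeds)
        samples[[idx]] <- sampleReads(ins$genome, config$readLength,
                                      config$coverage, id, cls)
        if (nrow(ins$insertions))
          truth[[idx]] <- cbind(sample_id = id, label = cls, ins$insertions)
      }
    }
    truth <- if (length(truth) && any(!vapply(truth, is.null, TRUE)))
      do.call(rbind, truth[!vapply(truth, is.null, TRUE)])
    else data.frame(sample_id = character(), label = integer(),
                    seed = character(), position = integer())
    structure(list(samples = samples, truth = truth, config = config),
              class = "SimulatedDataset")
  })
}

#' Write a simulated dataset to disk
#'
#' One FASTA (or FASTQ with uniform quality \code{"I"}) file per sample, a
#' sample sheet TSV (\code{sample_id}, \code{path}, \code{label}), the
#' ground-truth insertion table, and a JSON manifest echoing the
#' configuration and seed.
#'
#' @param dataset result of [generateDataset()].
#' @param outdir output directory (created if missing).
#' @param fastq write FASTQ instead of FASTA.
#' @return The sample sheet path, invisibly.
#' @export
writeSimulation <- function(dataset, outdir, fastq = FALSE) {
  if (!inherits(dataset, "SimulatedDataset"))
    stop("dataset must come from generateDataset()")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (fastq) "fastq" else "fasta"
  rows <- lapply(dataset$samples, function(rs) {
    path <- file.path(outdir, paste0(sampleId(rs), ".", ext))
    sq <- reads(rs)
    names(sq) <- sprintf("%s_read%05d", sampleId(rs), seq_along(sq))
    if (fastq) {
      Biostrings::writeXStringSet(sq, path, format = "fastq",
        qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(sq))))
    } else {
      Biostrings::writeXStringSet(sq, path)
    }
    data.frame(sample_id = sampleId(rs), path = path,
               label = sampleLabel(rs))
  })
  sheet <- do.call(rbind, rows)
  sheetPath <- file.path(outdir, "samples.tsv")
  utils::write.table(sheet, sheetPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$truth, file.path(outdir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- dataset$config
  manifest <- list(
    nPerClass = cfg$nPerClass, genomeLength = cfg$genomeLength,
    baseProbs = cfg$baseProbs, readLength = cfg$readLength,
    coverage = cfg$coverage, rngSeed = cfg$rngSeed,
    seedsClass1 = lapply(cfg$seedsClass1, unclass),
    seedsClass2 = lapply(cfg$seedsClass2, unclass),
    format = ext)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sheetPath)
}
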