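#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Sample-sheet and sequence-file I/O plus end-to-end experiment
## orchestration. Sequence files are FASTA or FASTQ, optionally gzipped;
## the sample sheet is a TSV with a header: sample_id, one or more path
## columns, and an optional label column with values 1/2 (empty allowed
## for unlabelled samples).
## ---------------------------------------------------------------------------

#' Read and validate a sample sheet
#'
#' @param path TSV file with header columns \code{sample_id},
#'   \code{path} (additional columns \code{path2}, \code{path3}, ... are
#'   allowed for samples split over several files) and optionally
#'   \code{label}.
#' @param checkFiles verify that every referenced sequence file exists.
#' @return A data.frame of class \code{"SampleSheet"}.
#' @export
readSampleSheet <- function(path, checkFiles = TRUE) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE)
  need <- c("sample_id", "path")
  if (!all(need %in% colnames(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1])
  pathCols <- grep("^path[0-9]*$", colnames(sheet), value = TRUE)
  if (checkFiles) {
    for (i in seq_len(nrow(sheet))) {
      files <- unlist(sheet[i, pathCols])
      files <- files[nzchar(files) & !is.na(files)]
      miss <- files[!file.exists(files)]
      if (length(miss))
        stop("row ", i, " (", sheet$sample_id[i], "): missing file ",
             miss[1])
    }
  }
  if ("label" %in% colnames(sheet)) {
    lab <- trimws(sheet$label)
    lab[!nzchar(lab)] <- NA
    bad <- !is.na(lab) & !lab %in% c("1", "2")
    if (any(bad))
      stop("row ", which(bad)[1], " (", sheet$sample_id[which(bad)[1]],
           "): label must be 1, 2 or empty, got '", lab[which(bad)[1]], "'")
    sheet$label <- as.integer(lab)
  } else {
    sheet$label <- NA_integer_
  }
  class(sheet) <- c("SampleSheet", "data.frame")
  sheet
}

## guess fasta/fastq from the (possibly .gz-stripped) extension
.seqFormat <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path)
  if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq" else "fasta"
}

#' Load the samples of a sheet as ReadSets
#'
#' Reads every sample's sequence files (FASTA/FASTQ, plain or gzipped),
#' concatenates multiple files per sample, filters reads containing
#' ambiguous bases and attaches the label.
#'
#' @param sheet a \code{"SampleSheet"} (from [readSampleSheet()]) or the
#'   path of one.
#' @return List of \linkS4class{ReadSet}.
#' @export
loadSamples <- function(sheet) {
  if (is.character(sheet)) sheet <- readSampleSheet(sheet)
  pathCols <- grep("^path[0-9]*$", colnames(sheet), value = TRUE)
  lapply(seq_len(nrow(sheet)), function(i) {
    files <- unlist(sheet[i, pathCols])
    files <- files[nzchar(files) & !is.na(files)]
    rd <- unlist(lapply(files, function(f) {
      as.character(Biostrings::readDNAStringSet(f, format = .seqFormat(f)))
    }))
    ReadSet(sheet$sample_id[i], rd, sheet$label[i])
  })
}

#' Write a count matrix as TSV
#'
#' Rows are samples, the header holds the k-tuple words; a leading
#' \code{sample_id} column identifies the rows. The transpose of the
#' internal storage, chosen for interoperability with spreadsheet-style
#' tools.
#'
#' @param x a \linkS4class{KTupleExperiment}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeCountMatrix <- function(x, path) {
  stopifnot(is(x, "KTupleExperiment"))
  m <- ktupleValues(x)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat key=value simulation config file
#'
#' Recognised keys mirror [simulationConfig()] /
#' [designSimulation()]: \code{n_per_class}, \code{genome_length},
#' \code{read_length}, \code{coverage}, \code{rng_seed},
#' \code{seed_length}, \code{density}, \code{n_seeds_class1},
#' \code{n_seeds_class2}, and optionally explicit comma-separated
#' \code{seeds_class1} / \code{seeds_class2} sequences. Lines starting
#' with \code{#} are comments.
#'
#' @param path config file path.
#' @return A \code{"SimulationConfig"}.
#' @export
readSimConfig <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line: ", ln[bad][1])
  vals <- stats::setNames(trimws(vapply(kv, `[[`, "", 2L)),
                          trimws(vapply(kv, `[[`, "", 1L)))
  num <- function(key, default) {
    if (key %in% names(vals)) as.numeric(vals[[key]]) else default
  }
  rngSeed <- as.integer(num("rng_seed", 1))
  density <- num("density", 0.01)
  common <- list(nPerClass = as.integer(num("n_per_class", 25)),
                 genomeLength = as.integer(num("genome_length", 10000)),
                 readLength = as.integer(num("read_length", 50)),
                 coverage = num("coverage", 10))
  explicit <- function(key) {
    if (!key %in% names(vals)) return(NULL)
    seqs <- strsplit(vals[[key]], ",", fixed = TRUE)[[1]]
    lapply(trimws(seqs), seedSpec, density = density)
  }
  s1 <- explicit("seeds_class1")
  s2 <- explicit("seeds_class2")
  if (is.null(s1) && is.null(s2)) {
    do.call(designSimulation,
            c(list(nSeeds1 = as.integer(num("n_seeds_class1", 0)),
                   nSeeds2 = as.integer(num("n_seeds_class2", 5)),
                   seedLength = as.integer(num("seed_length", 6)),
                   density = density, rngSeed = rngSeed), common))
  } else {
    do.call(simulationConfig,
            c(list(seedsClass1 = if (is.null(s1)) list() else s1,
                   seedsClass2 = if (is.null(s2)) list() else s2,
                   rngSeed = rngSeed), common))
  }
}

#' Run a full classification experiment end to end
#'
#' Orchestrates the complete pipeline for one dataset: obtain samples
#' (from a simulation config or a sample sheet), count k-tuples for every
#' k in the grid, run leakage-free LOOCV, apply the best-result rule, and
#' optionally write the results table, the best-result row and a JSON run
#' manifest to an output directory. Rerunning with an identical source and
#' seeds reproduces the outputs exactly.
#'
#' @param source a \code{"SimulationConfig"}, a \code{"SampleSheet"}, the
#'   path of a sample sheet, or a list of \linkS4class{ReadSet}.
#' @param kGrid integer vector of tuple lengths (each between 1 and 10).
#' @param baseLevels,cost,scope passed to [loocvCV2()].
#' @param maxLevel level cap for [bestResult()].
#' @param outdir optional output directory.
#' @return List with elements \code{cv} (list of \linkS4class{CV2Result}
#'   keyed by k), \code{results} (data.frame from [cvResultsTable()]),
#'   \code{best} (\linkS4class{BestResult}) and \code{samples}.
#' @export
runExperiment <- function(source, kGrid = 4:8,
                          baseLevels = defaultLadder(), cost = 1,
                          scope = "train_only", maxLevel = 200L,
                          outdir = NULL) {
  kGrid <- as.integer(kGrid)
  if (length(kGrid) == 0L) stop("kGrid must not be empty")
  if (any(kGrid < 1L | kGrid > .MAX_K)) stop("each k must lie in 1..10")
  samples <- if (inherits(source, "SimulationConfig")) {
    generateDataset(source)$samples
  } else if (inherits(source, "SampleSheet") || is.character(source)) {
    loadSamples(source)
  } else if (is.list(source) && all(vapply(source, is, TRUE, "ReadSet"))) {
    source
  } else stop("unsupported experiment source")
  cvs <- lapply(kGrid, function(k) {
    loocvCV2(toFrequencies(buildCountMatrix(samples, k)),
             baseLevels = baseLevels, cost = cost, scope = scope)
  })
  names(cvs) <- kGrid
  results <- cvResultsTable(cvs)
  best <- bestResult(cvs, maxLevel = maxLevel)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results, file.path(outdir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(k = best@k, level = best@level, accuracy = best@accuracy),
      file.path(outdir, "best.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    manifest <- list(kGrid = kGrid, baseLevels = baseLevels, cost = cost,
                     scope = scope, maxLevel = maxLevel,
                     nSamples = length(samples),
                     source = if (inherits(source, "SimulationConfig"))
                       list(type = "simulation", rngSeed = source$rngSeed)
                     else list(type = "samples"),
                     packageVersion =
                       as.character(utils::packageVersion("metaRSVM")))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cv = cvs, results = results, best = best, samples = samples)
}
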