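#' @include AllClasses.R
NULL

#' Benchmark simulation design grids
#'
#' The standard two-class benchmark sweeps. Design 1 inserts seeds into
#' class 2 only (class 1 is pure background), with 3, 5 or 10 seed kinds;
#' design 2 inserts distinct seed sets into both classes, with seed-count
#' pairs 1/1, 1/5, 5/5, 5/10 and 10/10. Each seed-count setting is crossed
#' with seed lengths 4, 5, 6 and 7, giving 12 experiments per design-1
#' density and 20 for design 2.
#'
#' @param design \code{"sim1"} (seeds in class 2 only) or \code{"sim2"}
#'   (seeds in both classes).
#' @param density per-seed insertion density (design 2 uses 0.01).
#' @return data.frame with columns \code{nSeeds1}, \code{nSeeds2},
#'   \code{seedLength}, \code{density}.
#' @export
benchmarkDesigns <- function(design = c("sim1", "sim2"), density = 0.01) {
  design <- match.arg(design)
  pairs <- if (design == "sim1") {
    list(c(0L, 3L), c(0L, 5L), c(0L, 10L))
  } else {
    list(c(1L, 1L), c(1L, 5L), c(5L, 5L), c(5L, 10L), c(10L, 10L))
  }
  grid <- expand.grid(pair = seq_along(pairs), seedLength = 4:7)
  data.frame(nSeeds1 = vapply(pairs, `[`, 0L, 1L)[grid$pair],
             nSeeds2 = vapply(pairs, `[`, 0L, 2L)[grid$pair],
             seedLength = grid$seedLength, density = density)
}

#' Run a benchmark sweep of simulation experiments
#'
#' For every design row, a dataset is simulated under the default
#' benchmark conditions (25 genomes per class, length 10,000, uniform
#' background, 50 bp error-free reads at 10-fold coverage), leakage-free
#' LOOCV is run over the k grid, and the best result is recorded.
#'
#' @param designs data.frame from [benchmarkDesigns()] (or with the same
#'   columns).
#' @param kGrid tuple lengths to evaluate per experiment.
#' @param rngSeed top-level seed; each experiment derives its own named
#'   stream from it.
#' @param maxLevel level cap for [bestResult()].
#' @param cost soft-margin penalty C.
#' @param verbose print one progress line per experiment.
#' @return \code{designs} with added columns \code{k}, \code{level},
#'   \code{accuracy} describing each experiment's best result.
#' @export
runBenchmarkSweep <- function(designs, kGrid = 4:7, rngSeed = 1L,
                              maxLevel = 200L, cost = 1,
                              verbose = interactive()) {
  out <- designs
  out$k <- out$level <- NA_integer_
  out$accuracy <- NA_real_
  for (i in seq_len(nrow(designs))) {
    d <- designs[i, ]
    tag <- sprintf("bench_%d_%d_%d_%g", d$nSeeds1, d$nSeeds2, d$seedLength,
                   d$density)
    cfg <- designSimulation(d$nSeeds1, d$nSeeds2, seedLength = d$seedLength,
                            density = d$density,
                            rngSeed = childSeed(rngSeed, tag))
    res <- runExperiment(cfg, kGrid = kGrid, cost = cost,
                         maxLevel = maxLevel)
    out$k[i] <- res$best@k
    out$level[i] <- res$best@level
    out$accuracy[i] <- res$best@accuracy
    if (verbose)
      message(sprintf("[%d/%d] %d/%d seeds l=%d d=%g -> k=%d level=%d acc=%.2f",
                      i, nrow(designs), d$nSeeds1, d$nSeeds2, d$seedLength,
                      d$density, res$best@k, res$best@level,
                      res$best@accuracy))
  }
  out
}
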