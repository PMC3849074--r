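test_that("background genomes follow the base model", {
  expect_identical(generateBackgroundGenome(10, c(1, 0, 0, 0)),
                   strrep("A", 10))
  set.seed(11)
  g <- generateBackgroundGenome(10000)
  expect_equal(nchar(g), 10000)
  freq <- table(factor(strsplit(g, "")[[1]], levels = DNA4)) / 10000
  expect_true(all(abs(freq - 0.25) < 0.02))  # binomial 99% band at n=1e4

  # composition converges to the base model: chi-square not rejected
  set.seed(12)
  gl <- generateBackgroundGenome(1e6, c(0.1, 0.2, 0.3, 0.4))
  tab <- table(factor(strsplit(gl, "")[[1]], levels = DNA4))
  expect_gt(chisq.test(tab, p = c(0.1, 0.2, 0.3, 0.4))$p.value, 0.001)

  expect_error(generateBackgroundGenome(0), "positive")
  expect_error(generateBackgroundGenome(10, c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
})

test_that("seed insertion count follows round(density * n / l) and conserves length", {
  set.seed(2)
  out <- insertSeeds(strrep("A", 10), list(seedSpec("CGT", 0.3)))
  expect_equal(nrow(out$insertions), 1L)          # 0.3*10/3 = 1 event
  expect_equal(nchar(out$genome), 10L)
  expect_true(grepl("CGT", out$genome))
  expect_true(out$insertions$position[1] %in% 1:8)

  n <- 10000
  g <- generateBackgroundGenome(n)
  expect_equal(nrow(insertSeeds(g, list(seedSpec("ACGTA", 0.01)))$insertions),
               20L)                                # 0.01*10000/5
  expect_equal(nrow(insertSeeds(g, list(seedSpec("ACGTAC", 0.005)))$insertions),
               8L)                                 # round(8.33)
  # half-way cases round away from zero
  expect_equal(nrow(insertSeeds(g, list(seedSpec("ACGT", 0.003)))$insertions),
               8L)                                 # round(7.5) -> 8
  expect_error(insertSeeds("ACG", list(seedSpec("ACGTA", 0.9))), "longer")
})

test_that("read sampling respects count, length and strand symmetry", {
  set.seed(3)
  g <- generateBackgroundGenome(10000)
  rs <- sampleReads(g, 50, 10, "s")
  expect_equal(length(reads(rs)), 2000L)           # round(10*10000/50)
  expect_true(all(Biostrings::width(reads(rs)) == 50))

  # over many reads each 3-tuple and its reverse complement appear with
  # near-equal frequency
  set.seed(4)
  big <- sampleReads(generateBackgroundGenome(20000), 50, 30, "big")
  cnt <- countKTuples(reads(big), 3)
  ratio <- cnt / cnt[rcOracle(names(cnt))]
  expect_true(all(abs(ratio - 1) < 0.15))

  expect_error(sampleReads("ACGT", 10, 5), "exceeds")
})

test_that("dataset generation is reproducible and correctly labelled", {
  cfg <- tinySimConfig(rngSeed = 9, nPerClass = 3)
  ds1 <- generateDataset(cfg)
  ds2 <- generateDataset(cfg)
  expect_equal(length(ds1$samples), 6L)
  expect_identical(lapply(ds1$samples, function(s) as.character(reads(s))),
                   lapply(ds2$samples, function(s) as.character(reads(s))))
  expect_identical(ds1$truth, ds2$truth)
  expect_equal(vapply(ds1$samples, sampleLabel, 1L), rep(1:2, each = 3))

  # class 1 has no insertions in a 0-vs-k design; class 2 has all of them
  expect_true(all(ds1$truth$label == 2L))
  # 0.03 * 600 / 4 = 4.5 insertion events, rounded away from zero to 5
  expect_equal(nrow(ds1$truth), 3L * 2L * 5L)            # 3 genomes x 2 seeds x 5 events

  # total base count: 2 N round(C n / beta) beta
  totalBases <- sum(vapply(ds1$samples,
                           function(s) sum(Biostrings::width(reads(s))), 0))
  expect_equal(totalBases, 2 * 3 * round(3 * 600 / 30) * 30)

  one <- generateDataset(simulationConfig(nPerClass = 1, genomeLength = 200,
                                          readLength = 20, coverage = 2,
                                          rngSeed = 1))
  expect_equal(length(one$samples), 2L)
})

test_that("the default configuration encodes the benchmark conditions", {
  cfg <- simulationConfig()
  expect_equal(cfg$nPerClass, 25L)
  expect_equal(cfg$genomeLength, 10000L)
  expect_equal(cfg$readLength, 50L)
  expect_equal(cfg$coverage, 10)
  expect_equal(cfg$baseProbs, rep(0.25, 4))
  expect_error(simulationConfig(genomeLength = 30, readLength = 50),
               "readLength")
  expect_error(
    simulationConfig(seedsClass2 = list(seedSpec("ACGTACGTAC", 1e-4))),
    "density too low")
})

test_that("written simulations round-trip and are byte-identical on rerun", {
  cfg <- tinySimConfig(rngSeed = 5, nPerClass = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sheet1 <- writeSimulation(generateDataset(cfg), d1)
  sheet2 <- writeSimulation(generateDataset(cfg), d2)
  f1 <- list.files(d1, pattern = "fasta$", full.names = TRUE)
  f2 <- list.files(d2, pattern = "fasta$", full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  sheet <- readSampleSheet(sheet1)
  expect_equal(nrow(sheet), 4L)
  loaded <- loadSamples(sheet)
  orig <- generateDataset(cfg)$samples
  expect_identical(lapply(loaded, function(s) as.character(reads(s))),
                   lapply(orig, function(s) as.character(reads(s))))
  expect_identical(vapply(loaded, sampleLabel, 1L),
                   vapply(orig, sampleLabel, 1L))
})
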