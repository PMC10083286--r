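test_that("pure-core alleles are exact", {
  a <- generateAllele(4, interruptionFraction = 0, seed = 1)
  expect_identical(alleleTokens(a), rep("GGCCTG", 4))
  expect_identical(tract(a), strrep("GGCCTG", 4))
  expect_identical(coreCount(a), 4L)

  a650 <- generateAllele(650, interruptionFraction = 0, seed = 7)
  expect_identical(tractLength(a650), 3900L)
  expect_identical(coreCount(a650), 650L)
})

test_that("interrupted alleles hit the target composition", {
  a <- generateAllele(700, interruptionFraction = 0.2, seed = 42)
  toks <- alleleTokens(a)
  expect_identical(length(toks), 875L)  # 700 / 0.8
  ## oracle: direct tally of emitted tokens
  expect_identical(coreCount(a), sum(toks == "GGCCTG"))
  ## binomial 99% interval around 0.8 * token count
  sd <- sqrt(875 * 0.8 * 0.2)
  expect_lt(abs(coreCount(a) - 700), 2.576 * sd + 1)
  expect_error(generateAllele(10, interruptionFraction = 1), "\\[0, 1\\)")
  expect_error(generateAllele(10, variantWeights = c(1, 1, 1, 1)),
               "summing to 1")
})

test_that("variant composition recovers configured weights (3-sigma)", {
  w <- c(0.5, 0.3, 0.15, 0.05)
  a <- generateAllele(1600, interruptionFraction = 0.5,
                      variantWeights = w, seed = 9)
  toks <- alleleTokens(a)
  vars <- variantMotifs(MotifCatalog())
  nVar <- sum(toks != "GGCCTG")
  for (i in seq_along(vars)) {
    phat <- sum(toks == vars[i]) / nVar
    expect_lt(abs(phat - w[i]), 3 * sqrt(w[i] * (1 - w[i]) / nVar) + 1e-9)
  }
})

test_that("locus embedding places the repeat interval correctly", {
  fl <- randomFlanks(50, seed = 1)
  loc <- generateLocus(RepeatAllele(rep("GGCCTG", 3)), fl$left, fl$right)
  expect_identical(unname(repeatInterval(loc)), c(50L, 68L))
  expect_identical(nchar(locusSeq(loc)), 118L)
  expect_identical(substr(locusSeq(loc), 51, 68), strrep("GGCCTG", 3))

  fl200 <- randomFlanks(200, seed = 5)
  a <- generateAllele(30, 0.1, seed = 6)
  loc2 <- generateLocus(a, fl200$left, fl200$right)
  expect_identical(nchar(locusSeq(loc2)), 400L + tractLength(a))
})

test_that("locus construction rejects broken flanks", {
  fl <- randomFlanks(50, seed = 2)
  a <- RepeatAllele(rep("GGCCTG", 3))
  expect_error(generateLocus(a, fl$left, ""), "non-empty")
  bad <- paste0(strrep("GGCCTG", 2), fl$left)
  expect_error(generateLocus(a, bad, fl$right), "run of >= 2")
  expect_error(generateLocus(a, substr(fl$left, 1, 20), fl$right),
               "at least 30")
})

test_that("error-free full-locus reads reconstruct the locus", {
  fl <- testFlanks()
  loc <- generateLocus(generateAllele(50, seed = 3), fl$left, fl$right)
  rd <- simulateReads(loc, coverage = 5, errorRate = 0,
                      readLength = list(type = "fixed", length = NA),
                      seed = 4)
  mc <- S4Vectors::mcols(rd)
  for (i in seq_along(rd)) {
    seq <- as.character(rd[[i]])
    expect_identical(if (mc$strand[i] == "-") revComp(seq) else seq,
                     locusSeq(loc))
  }
  expect_true(all(mc$true_class %in% c("full_dGGCCTGn", "full_dGGCCTGr")))
})

test_that("strandFraction 1 puts every read on the minus strand", {
  fl <- testFlanks()
  loc <- generateLocus(generateAllele(20, seed = 1), fl$left, fl$right)
  rd <- simulateReads(loc, coverage = 3, errorRate = 0,
                      strandFraction = 1, seed = 5)
  expect_true(all(S4Vectors::mcols(rd)$strand == "-"))
})

test_that("realized error rate matches the configured rate", {
  fl <- randomFlanks(100, seed = 8)
  loc <- generateLocus(generateAllele(100, seed = 8), fl$left, fl$right)
  rd <- simulateReads(loc, coverage = 110, errorRate = 0.12,
                      readLength = list(type = "fixed", length = 800),
                      seed = 9)
  expect_gte(length(rd), 100L)
  mc <- S4Vectors::mcols(rd)
  rates <- vapply(seq_along(rd), function(i) {
    truth <- if (mc$strand[i] == "-") revComp(mc$true_fragment[i]) else
      mc$true_fragment[i]
    oracleEditDistance(as.character(rd[[i]]), truth) / nchar(truth)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.12), 0.02)
})

test_that("identical seeds give byte-identical FASTQ; truth partitions", {
  fl <- testFlanks()
  loc <- generateLocus(generateAllele(30, 0.1, seed = 2), fl$left,
                       fl$right)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeReadsFastq(simulateReads(loc, coverage = 4, seed = 77), f1)
  writeReadsFastq(simulateReads(loc, coverage = 4, seed = 77), f2)
  expect_identical(readLines(f1), readLines(f2))

  rd <- simulateReads(loc, coverage = 6, seed = 78)
  tt <- truthTable(rd)
  expect_identical(nrow(tt), length(rd))
  expect_true(all(tt$true_class %in% c("full_dGGCCTGn", "5p_GGCCTGn",
                                       "3p_GGCCTGn", "full_dGGCCTGr",
                                       "non_spanning")))
})

test_that("parameter validation rejects bad simulation settings", {
  fl <- testFlanks()
  loc <- generateLocus(generateAllele(10, seed = 1), fl$left, fl$right)
  expect_error(simulateReads(loc, coverage = 0), "coverage")
  expect_error(simulateReads(loc, errorRate = 0.6), "errorRate")
  expect_error(simulateReads(loc, errorMix = c(1, 1, 1)), "errorMix")
  expect_error(simulateReads(loc, strandFraction = 2), "strandFraction")
})
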