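test_that("core repeat counting is exact on clean tracts", {
  expect_identical(countCoreRepeats(strrep("GGCCTG", 4)), 4L)
  expect_identical(countCoreRepeats(""), 0L)
  expect_identical(countCoreRepeats(NA_character_), NA_integer_)
  expect_error(countCoreRepeats("GGXCTG"), "A/C/G/T")

  ## 120 cores with 15 interspersed variants: oracle = generator tally
  a <- generateAllele(120, interruptionFraction = 15 / 135, seed = 13)
  expect_identical(countCoreRepeats(tract(a)),
                   sum(alleleTokens(a) == "GGCCTG"))
  expect_identical(countCoreRepeats(tract(a), mode = "exact"),
                   sum(alleleTokens(a) == "GGCCTG"))
})

test_that("exact mode counts non-overlapping occurrences left-greedily", {
  expect_identical(countCoreRepeats(paste0("GGCCTG", "AAA", "GGCCTG"),
                                    mode = "exact"), 2L)
  expect_identical(countCoreRepeats("GGCCT", mode = "exact"), 0L)
})

test_that("pathogenic threshold is strictly greater-than", {
  expect_false(isPathogenic(650))
  expect_true(isPathogenic(651))
  expect_true(isPathogenic(746))
  expect_error(isPathogenic(-1), ">= 0")
})

test_that("reported ratio reproduces the published sample cells", {
  expect_equal(pathogenicRatio(9, 76), 11.84)
  expect_equal(pathogenicRatio(23, 162), 14.20)
  expect_equal(pathogenicRatio(20, 96), 20.83)
  expect_equal(pathogenicRatio(0, 0), 0)
})

test_that("ratio is bounded and monotone in the numerator", {
  for (n in c(0, 5, 33, 76)) {
    r <- pathogenicRatio(n, 76)
    expect_gte(r, 0); expect_lte(r, 100)
  }
  rs <- vapply(0:10, pathogenicRatio, numeric(1), subreads = 40)
  expect_true(all(diff(rs) >= 0))
})

test_that("sample summary aggregates spanning and full-length reads", {
  mk <- function(cls, tract) data.frame(span_class = cls, tract = tract,
                                        stringsAsFactors = FALSE)
  cl <- rbind(
    mk("full_dGGCCTGn", strrep("GGCCTG", 700)),
    mk("full_dGGCCTGr", strrep("GGCCTG", 600)),
    mk("5p_GGCCTGn", strrep("GGCCTG", 660)),
    mk("3p_GGCCTGn", strrep("GGCCTG", 100)),
    mk("non_spanning", NA_character_))
  s <- summarizeSample(cl, sampleId = "T", countMode = "exact")
  expect_identical(s$subread_number, 4L)      # all spanning classes
  expect_identical(s$n_650plus, 2L)           # 700 and 660 exceed 650
  expect_equal(s$ratio_650plus, 50)
  expect_identical(s$full_count, 2L)
  expect_identical(s$full_fwd, 1L); expect_identical(s$full_rev, 1L)
  ## full-length-only statistics
  expect_identical(s$max_repeats, 700L)
  expect_identical(s$min_repeats, 600L)
  expect_identical(s$mean_repeats, 650L)
  expect_identical(s$max_length_bp, 4200L)
  expect_identical(s$min_length_bp, 3600L)
  expect_true(s$min_length_bp <= s$mean_length_bp &&
                s$mean_length_bp <= s$max_length_bp)
})

test_that("a sample without spanning reads reports zeros with a warning", {
  cl <- data.frame(span_class = "non_spanning", tract = NA_character_)
  expect_warning(s <- summarizeSample(cl, "empty"), "no spanning")
  expect_identical(s$subread_number, 0L)
  expect_identical(s$ratio_650plus, 0)
})

test_that("summary TSV follows the report column order", {
  cl <- data.frame(span_class = "full_dGGCCTGn",
                   tract = strrep("GGCCTG", 10))
  s <- summarizeSamples(list(summarizeSample(cl, "A", countMode = "exact")))
  path <- tempfile(fileext = ".tsv")
  writeSummaryTsv(s, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_identical(hdr[1:5], c("Sample ID", "Subread number",
                               "dGGCCTG 650+", "dGGCCTG 650+ ratio",
                               "Full dGGCCTGn"))
  expect_true(file.exists(paste0(path, ".json")))
})
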