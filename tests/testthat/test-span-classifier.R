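test_that("exact anchor embeddings are found at distance 0", {
  cs <- anchorConstruct(nCore = 10)
  hits <- findAnchors(cs$read, cs$anchors$left, cs$anchors$right,
                      maxEditFraction = 0)
  plus <- hits[hits$strand == "+", ]
  expect_identical(nrow(plus), 2L)
  expect_true(all(plus$edit_distance == 0))
  l <- plus[plus$which == "left", ]; r <- plus[plus$which == "right", ]
  expect_identical(c(l$read_start, l$read_end), c(0L, 30L))
  expect_identical(c(r$read_start, r$read_end), c(90L, 120L))
})

test_that("anchor hits are strand-symmetric under reverse complement", {
  cs <- anchorConstruct(nCore = 10)
  hits <- findAnchors(revComp(cs$read), cs$anchors$left, cs$anchors$right,
                      maxEditFraction = 0)
  minus <- hits[hits$strand == "-", ]
  expect_identical(nrow(minus), 2L)
  ## minus coordinates are on the reverse-complemented read = original
  l <- minus[minus$which == "left", ]
  expect_identical(c(l$read_start, l$read_end), c(0L, 30L))
})

test_that("noisy anchors agree with the infix-alignment oracle", {
  fl <- testFlanks()
  anc <- flankAnchors(fl$left, fl$right)
  set.seed(31)
  for (i in 1:12) {
    read <- paste0(anc$left, strrep("GGCCTG", 40), anc$right)
    noisy <- RepeatSpan:::.injectErrors(read, 0.12,
                                        c(sub = .25, ins = .45, del = .30))
    hits <- findAnchors(noisy, anc$left, anc$right)
    for (which in c("left", "right")) {
      d <- oracleInfixDistance(anc[[which]], noisy)
      h <- hits[hits$which == which & hits$strand == "+", ]
      if (d <= 8) {
        expect_identical(h$edit_distance, as.integer(d))
      } else {
        expect_identical(nrow(h), 0L)
      }
    }
  }
})

test_that("classification rules map anchor patterns to span classes", {
  cs <- anchorConstruct(nCore = 10)
  hits <- findAnchors(cs$read, cs$anchors$left, cs$anchors$right)
  expect_identical(classifyRead(hits, nchar(cs$read)), "full_dGGCCTGn")
  hitsRc <- findAnchors(revComp(cs$read), cs$anchors$left,
                        cs$anchors$right)
  expect_identical(classifyRead(hitsRc, nchar(cs$read)), "full_dGGCCTGr")

  ## left anchor + 300 bp of repeat only -> 5' partial
  p5 <- paste0(cs$anchors$left, strrep("GGCCTG", 50))
  h5 <- findAnchors(p5, cs$anchors$left, cs$anchors$right)
  expect_identical(classifyRead(h5, nchar(p5)), "5p_GGCCTGn")
  expect_identical(classifyRead(findAnchors(revComp(p5), cs$anchors$left,
                                            cs$anchors$right),
                                nchar(p5)), "3p_GGCCTGn")

  ## repeat + right anchor -> 3' partial
  p3 <- paste0(strrep("GGCCTG", 50), cs$anchors$right)
  h3 <- findAnchors(p3, cs$anchors$left, cs$anchors$right)
  expect_identical(classifyRead(h3, nchar(p3)), "3p_GGCCTGn")

  ## no anchors at all
  expect_identical(classifyRead(findAnchors(strrep("GGCCTG", 30),
                                            cs$anchors$left,
                                            cs$anchors$right), 180),
                   "non_spanning")
})

test_that("contradictory anchor order is non-spanning with a warning", {
  hits <- data.frame(which = c("left", "right"), strand = "+",
                     read_start = c(100L, 0L), read_end = c(130L, 30L),
                     edit_distance = 0L)
  expect_warning(cls <- classifyRead(hits, 200), "contradictory")
  expect_identical(cls, "non_spanning")
})

test_that("tract extraction is exact and strand-normalized", {
  cs <- anchorConstruct(nCore = 10)
  hits <- findAnchors(cs$read, cs$anchors$left, cs$anchors$right)
  expect_identical(extractTract(cs$read, hits), strrep("GGCCTG", 10))
  rc <- revComp(cs$read)
  hitsRc <- findAnchors(rc, cs$anchors$left, cs$anchors$right)
  expect_identical(extractTract(rc, hitsRc), strrep("GGCCTG", 10))

  p5 <- paste0(cs$anchors$left, strrep("GGCCTG", 5))
  h5 <- findAnchors(p5, cs$anchors$left, cs$anchors$right)
  expect_identical(extractTract(p5, h5), strrep("GGCCTG", 5))
})

test_that("error-free simulated reads classify to truth with exact tracts", {
  fl <- testFlanks()
  allele <- generateAllele(80, 0.1, seed = 21)
  loc <- generateLocus(allele, fl$left, fl$right)
  rd <- simulateReads(loc, coverage = 8, errorRate = 0, seed = 22,
                      readLength = list(type = "lognormal",
                                        meanlog = log(600), sdlog = 0.6,
                                        min = 100))
  cl <- classifyReads(rd, fl$left, fl$right)
  tt <- truthTable(rd)
  expect_identical(cl$span_class, tt$true_class)
  full <- cl$span_class %in% c("full_dGGCCTGn", "full_dGGCCTGr")
  if (any(full))
    expect_true(all(cl$tract[full] == tract(allele)))
  ## partition: every read gets exactly one class
  expect_identical(sum(classCounts(cl)), nrow(cl))
})
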