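test_that("exact catalog concatenations tokenize at cost zero", {
  cat6 <- testCatalog()
  tok <- tokenize(strrep("GGCCTG", 3), cat6)
  expect_identical(tokenLabels(tok), rep("GGCCTG", 3))
  expect_identical(totalCost(tok), 0L)

  tok2 <- tokenize(paste0("GGCCTG", "GGCTG", "GGCCTG"), cat6)
  expect_identical(tokenLabels(tok2), c("GGCCTG", "GGCTG", "GGCCTG"))
  expect_identical(totalCost(tok2), 0L)
  expect_identical(unassignedBases(tok2), 0L)
})

test_that("token intervals tile the tract exactly", {
  cat6 <- testCatalog()
  set.seed(101)
  for (i in 1:20) {
    rc <- randomConcat(60)
    seq <- if (i %% 2 == 0) injectOneSub(rc$seq) else rc$seq
    tok <- tokenize(seq, cat6)
    tk <- tokenTable(tok)
    expect_identical(tk$start[1], 0L)
    expect_identical(tk$end[nrow(tk)], nchar(seq))
    expect_identical(sum(tk$end - tk$start), nchar(seq))
    if (nrow(tk) > 1)
      expect_identical(tk$start[-1], tk$end[-nrow(tk)])
  }
})

test_that("DP cost equals the exhaustive-tiling oracle on small tracts", {
  cat6 <- testCatalog()
  motifs <- catalogMotifs(cat6)
  set.seed(55)
  for (i in 1:40) {
    rc <- randomConcat(60)
    seq <- if (i %% 2 == 0) injectOneSub(rc$seq) else rc$seq
    tok <- tokenize(seq, cat6)
    or <- oracleTiling(seq, motifs)
    expect_identical(totalCost(tok), as.integer(or$cost))
    ## a substitution can create an exact alternative parse (cost 0), so
    ## generating labels are only required when the unique optimum costs
    ## what the generating tiling costs
    if (or$count == 1 && or$cost == (if (i %% 2 == 0) 1L else 0L))
      expect_identical(tokenLabels(tok), rc$tokens)
  }
})

test_that("tokenization is stable across repeated runs", {
  cat6 <- testCatalog()
  set.seed(7)
  rc <- randomConcat(60)
  seq <- injectOneSub(rc$seq)
  expect_identical(tokenTable(tokenize(seq, cat6)),
                   tokenTable(tokenize(seq, cat6)))
})

test_that("unexplained bases become merged 'other' runs", {
  cat6 <- testCatalog()
  ## a long non-catalog insert between two clean cores
  seq <- paste0("GGCCTG", "TTTTTTTTTTTT", "GGCCTG")
  tok <- tokenize(seq, cat6)
  tk <- tokenTable(tok)
  expect_identical(tk$label[c(1, nrow(tk))], c("GGCCTG", "GGCCTG"))
  expect_true(any(tk$label == "other"))
  expect_identical(unassignedBases(tok),
                   sum((tk$end - tk$start)[tk$label == "other"]))
})

test_that("motif nucleotide ratios normalize and match hand computation", {
  cat6 <- testCatalog()
  t1 <- motifRatios(tokenize(strrep("GGCCTG", 10), cat6))
  expect_identical(t1$label[t1$group == "all"], "GGCCTG")
  expect_equal(t1$percent[t1$group == "all"], 100)

  t2 <- motifRatios(tokenize(paste0("GGCCTG", "GGCTG"), cat6))
  all2 <- t2[t2$group == "all", ]
  expect_equal(all2$percent[all2$label == "GGCCTG"], 600 / 11,
               tolerance = 1e-10)
  expect_equal(all2$percent[all2$label == "GGCTG"], 500 / 11,
               tolerance = 1e-10)
  expect_equal(sum(all2$percent), 100, tolerance = 0.01)
  expect_equal(roundHalfUp(all2$percent, 2), c(54.55, 45.45))
})

test_that("pooled ratios over clean tracts equal generator tallies", {
  cat6 <- testCatalog()
  alleles <- lapply(1:5, function(i)
    generateAllele(100, 0.2, catalog = cat6, seed = 200 + i))
  toks <- lapply(alleles, function(a) tokenize(tract(a), cat6))
  rt <- motifRatios(toks, scope = "pooled")
  all <- rt[rt$group == "all", ]
  truthNt <- table(unlist(lapply(alleles, alleleTokens)))
  truthNt <- setNames(as.integer(truthNt) * nchar(names(truthNt)),
                      names(truthNt))
  for (lab in names(truthNt))
    expect_identical(all$nucleotides[all$label == lab],
                     unname(truthNt[lab]))
  expect_equal(sum(all$percent), 100, tolerance = 0.01)
})

test_that("top motifs rank by percentage with deterministic ties", {
  tab <- data.frame(label = c("GGCCTG", "GGCTG", "GGCCG"),
                    length_nt = c(6L, 5L, 5L),
                    nucleotides = c(80L, 15L, 5L),
                    percent = c(80, 15, 5), group = "all")
  expect_identical(topMotifs(tab, k = 2), c("GGCCTG", "GGCTG"))
  expect_identical(topMotifs(tab, k = 10, lengthFilter = 7), character(0))
  tie <- data.frame(label = c("BBBB", "AAAA"), length_nt = 4L,
                    nucleotides = 50L, percent = 50, group = "all")
  expect_identical(topMotifs(tie), c("AAAA", "BBBB"))
})

test_that("rare motif labels use a strict threshold", {
  tab <- data.frame(label = c("GGCCTG", "X1", "X2"),
                    length_nt = c(6L, 5L, 5L),
                    nucleotides = c(990L, 8L, 10L),
                    percent = c(98.2, 0.8, 1.0), group = "all")
  expect_identical(rareMotifLabels(tab), "X1")
  tab$percent <- c(99.0, 1.0, 1.0)  # nothing strictly below 1
  expect_identical(rareMotifLabels(tab[-2, ]), character(0))
})

test_that("recurring unexplained segments are promoted to literal labels", {
  cat6 <- testCatalog()
  novel <- "TTTTAACGAT"  # 10 bp, far from every catalog motif
  seqs <- replicate(3, paste0(strrep("GGCCTG", 6), novel,
                              strrep("GGCCTG", 6)))
  toks <- lapply(seqs, tokenize, catalog = cat6)
  ## the recurring unexplained run as the tokenizer actually reports it
  tk <- tokenTable(toks[[1]])
  w <- tk$end - tk$start
  segs <- substring(seqs[1], tk$start + 1,
                    tk$end)[tk$label == "other" & w >= 4 & w <= 8]
  expect_gte(length(segs), 1L)
  rt <- motifRatios(toks, scope = "pooled", promoteNovel = TRUE)
  expect_true(all(segs %in% rt$label))
  rtOff <- motifRatios(toks, scope = "pooled", promoteNovel = FALSE)
  expect_false(any(segs %in% rtOff$label))
})
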