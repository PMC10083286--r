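## Independent oracles and shared fixtures for the test suite.

suppressPackageStartupMessages(library(Biostrings))

## Optimal infix (semi-global) edit distance of `anchor` against any
## substring of `read`, via pairwiseAlignment with unit costs -- an
## implementation independent of the package's DP.
oracleInfixDistance <- function(anchor, read) {
  mat <- nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  -BiocGenerics::score(pairwiseAlignment(
    anchor, read, type = "global-local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1))
}

## Global edit distance between two sequences (utils::adist).
oracleEditDistance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

## Minimum tiling cost over all tilings of `tractSeq` with catalog motifs
## (steps of unitMin..unitMax bases at the best motif's edit distance,
## capped, or a 1-base fallback at cost 1), by recursive enumeration with
## suffix memoisation. Also counts the distinct optimal step/label
## sequences, so ambiguity is detectable.
oracleTiling <- function(tractSeq, motifs, unitMin = 4, unitMax = 8,
                         maxUnitCost = 2) {
  n <- nchar(tractSeq)
  memo <- vector("list", n + 1L)
  solve <- function(i) {
    if (i == n) return(list(cost = 0, count = 1))
    if (!is.null(memo[[i + 1L]])) return(memo[[i + 1L]])
    best <- Inf; cnt <- 0
    r <- solve(i + 1L)                      # fallback step
    if (1 + r$cost < best) { best <- 1 + r$cost; cnt <- r$count }
    else if (1 + r$cost == best) cnt <- cnt + r$count
    for (u in unitMin:unitMax) {
      if (i + u > n) break
      seg <- substr(tractSeq, i + 1L, i + u)
      d <- as.integer(utils::adist(seg, motifs))
      dm <- min(d)
      if (dm > maxUnitCost) next
      r <- solve(i + u)
      if (dm + r$cost < best) {
        best <- dm + r$cost
        cnt <- sum(d == dm) * r$count
      } else if (dm + r$cost == best) {
        cnt <- cnt + sum(d == dm) * r$count
      }
    }
    memo[[i + 1L]] <<- list(cost = best, count = cnt)
    memo[[i + 1L]]
  }
  solve(0L)
}

## Small shared fixtures
testCatalog <- function() MotifCatalog()

testFlanks <- function() bundledFlanks()

## A deterministic exact read construct: left anchor + n core units +
## right anchor.
anchorConstruct <- function(nCore = 10, anchorK = 30) {
  fl <- testFlanks()
  anc <- flankAnchors(fl$left, fl$right, anchorK)
  list(read = paste0(anc$left, strrep("GGCCTG", nCore), anc$right),
       anchors = anc, nCore = nCore, anchorK = anchorK)
}

## Random concatenation of catalog motifs, seed-fixed; returns the token
## list and the sequence.
randomConcat <- function(maxLen = 60, catalog = testCatalog()) {
  motifs <- catalogMotifs(catalog)
  toks <- character(0)
  len <- 0L
  repeat {
    m <- sample(motifs, 1L, prob = c(0.6, rep(0.1, length(motifs) - 1L)))
    if (len + nchar(m) > maxLen) break
    toks <- c(toks, m)
    len <- len + nchar(m)
  }
  if (!length(toks)) toks <- motifs[1L]
  list(tokens = toks, seq = paste(toks, collapse = ""))
}

## Inject exactly one random substitution into a sequence.
injectOneSub <- function(seq) {
  bases <- c("A", "C", "G", "T")
  i <- sample(nchar(seq), 1L)
  old <- substr(seq, i, i)
  substr(seq, i, i) <- sample(setdiff(bases, old), 1L)
  seq
}

classCounts <- function(classified) {
  table(factor(classified$span_class,
               levels = c("full_dGGCCTGn", "5p_GGCCTGn", "3p_GGCCTGn",
                          "full_dGGCCTGr", "non_spanning")))
}
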