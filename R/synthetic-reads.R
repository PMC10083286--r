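#' RepeatLocus: a repeat tract embedded between unique flanks
#'
#' The simulated (or user-supplied) locus sequence together with the
#' 0-based half-open interval of its repeat tract and, when known, the
#' ground-truth motif tokens of the tract.
#'
#' @slot locus Full locus sequence (left flank + tract + right flank).
#' @slot repeatStart,repeatEnd 0-based half-open tract interval.
#' @slot tokens Ground-truth motif tokens (may be empty when unknown).
#' @slot core Core motif.
#'
#' @seealso [generateLocus()], [simulateReads()]
#' @name RepeatLocus-class
#' @exportClass RepeatLocus
setClass("RepeatLocus",
  representation(locus = "character", repeatStart = "integer",
                 repeatEnd = "integer", tokens = "character",
                 core = "character"))

setValidity("RepeatLocus", function(object) {
  msg <- character(0)
  if (grepl("[^ACGT]", object@locus))
    msg <- c(msg, "locus must be uppercase ACGT")
  if (object@repeatStart < 0L || object@repeatEnd > nchar(object@locus) ||
      object@repeatStart > object@repeatEnd)
    msg <- c(msg, "repeat interval out of bounds")
  if (length(object@tokens) &&
      sum(nchar(object@tokens)) != object@repeatEnd - object@repeatStart)
    msg <- c(msg, "tokens do not tile the repeat interval")
  if (length(msg)) msg else TRUE
})

#' @describeIn RepeatLocus-class Locus sequence as a character string.
#' @param x A `RepeatLocus`.
#' @export
setGeneric("locusSeq", function(x) standardGeneric("locusSeq"))

#' @rdname RepeatLocus-class
#' @export
setMethod("locusSeq", "RepeatLocus", function(x) x@locus)

#' @describeIn RepeatLocus-class 0-based half-open repeat interval.
#' @export
setGeneric("repeatInterval", function(x) standardGeneric("repeatInterval"))

#' @rdname RepeatLocus-class
#' @export
setMethod("repeatInterval", "RepeatLocus",
          function(x) c(start = x@repeatStart, end = x@repeatEnd))

setMethod("show", "RepeatLocus", function(object) {
  cat("RepeatLocus:", nchar(object@locus), "bp, repeat [",
      object@repeatStart, ",", object@repeatEnd, ")\n")
})

#' Generate a repeat allele with random interruptions
#'
#' Draws an ordered token list emulating an expanded, interrupted repeat
#' tract: each token is independently the core motif with probability
#' `1 - interruptionFraction`, otherwise a variant motif drawn by weight.
#' The token count is `round(nCoreTarget / (1 - interruptionFraction))`, so
#' the expected number of core tokens equals `nCoreTarget`.
#'
#' @param nCoreTarget Target (expected) core repeat count; >= 1.
#' @param interruptionFraction Fraction of tokens that are interruptions,
#'   in `[0, 1)`.
#' @param catalog A [MotifCatalog-class].
#' @param variantWeights Per-variant probabilities (summing to 1); default
#'   uniform over the catalog variants.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @return A [RepeatAllele-class].
#' @examples
#' a <- generateAllele(650, seed = 7)
#' tractLength(a)  # 3900
#' @export
generateAllele <- function(nCoreTarget, interruptionFraction = 0,
                           catalog = MotifCatalog(),
                           variantWeights = NULL, seed = NULL) {
  if (!is.numeric(nCoreTarget) || nCoreTarget < 1)
    stop("'nCoreTarget' must be >= 1")
  if (interruptionFraction < 0 || interruptionFraction >= 1)
    stop("'interruptionFraction' must lie in [0, 1)")
  variants <- variantMotifs(catalog)
  if (is.null(variantWeights))
    variantWeights <- rep(1 / length(variants), length(variants))
  if (length(variantWeights) != length(variants) ||
      any(variantWeights < 0) || abs(sum(variantWeights) - 1) > 1e-6)
    stop("'variantWeights' must be per-variant probabilities summing to 1")
  nTokens <- max(1L, as.integer(round(nCoreTarget /
                                        (1 - interruptionFraction))))
  withSeed(seed, {
    isVar <- runif(nTokens) < interruptionFraction
    tokens <- rep(coreMotif(catalog), nTokens)
    if (any(isVar))
      tokens[isVar] <- sample(variants, sum(isVar), replace = TRUE,
                              prob = variantWeights)
    RepeatAllele(tokens, core = coreMotif(catalog))
  })
}

#' Generate random flank sequences free of core-motif runs
#'
#' @param n Flank length in bp (each side).
#' @param seed Integer seed.
#' @param core Core motif the flanks must not contain a run (>= 2 copies)
#'   of, so flank anchors stay unique.
#' @return `list(left =, right =)` of DNA strings.
#' @export
randomFlanks <- function(n = 300, seed = 1, core = "GGCCTG") {
  run2 <- strrep(core, 2)
  withSeed(seed, {
    draw <- function() {
      repeat {
        x <- randomDna(n)
        if (!grepl(run2, x, fixed = TRUE)) return(x)
      }
    }
    list(left = draw(), right = draw())
  })
}

#' Embed an allele's tract between flanks
#'
#' @param allele A [RepeatAllele-class].
#' @param leftFlank,rightFlank Unique flanking sequences; each must be at
#'   least `anchorK` bp and contain no run of >= 2 core motifs (which would
#'   break flank anchoring).
#' @param anchorK Anchor length the flanks must support (default 30).
#' @return A [RepeatLocus-class]; the repeat interval is
#'   `[nchar(leftFlank), nchar(leftFlank) + tractLength(allele))`.
#' @examples
#' fl <- randomFlanks(50, seed = 1)
#' loc <- generateLocus(RepeatAllele(rep("GGCCTG", 3)), fl$left, fl$right)
#' repeatInterval(loc)
#' @export
generateLocus <- function(allele, leftFlank, rightFlank, anchorK = 30) {
  assertDna(leftFlank, "leftFlank")
  assertDna(rightFlank, "rightFlank")
  core <- allele@core
  run2 <- strrep(core, 2)
  for (fl in c(left = leftFlank, right = rightFlank)) {
    if (nchar(fl) < anchorK)
      stop("flanks must be at least ", anchorK, " bp")
    if (grepl(run2, fl, fixed = TRUE))
      stop("flank contains a run of >= 2 core motifs; anchoring would break")
  }
  tr <- tract(allele)
  new("RepeatLocus",
      locus = paste0(leftFlank, tr, rightFlank),
      repeatStart = nchar(leftFlank),
      repeatEnd = nchar(leftFlank) + nchar(tr),
      tokens = alleleTokens(allele), core = core)
}

## interval overlap length for 0-based half-open intervals
.ovl <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1))

## Truth span class of a fragment [fs, fe) over a locus, BEFORE errors.
## A flank anchor counts as covered iff the fragment overlaps at least
## K - ceil(maxEditFraction * K) of its K bp -- the same detectability
## geometry the classifier applies, so truth is well defined at error 0.
.truthClass <- function(fs, fe, rs, re, strand, anchorK, maxEditFraction,
                        minTractBp) {
  need <- anchorK - as.integer(ceiling(maxEditFraction * anchorK))
  leftCov <- .ovl(fs, fe, rs - anchorK, rs) >= need
  rightCov <- .ovl(fs, fe, re, re + anchorK) >= need
  tractOv <- .ovl(fs, fe, rs, re)
  if (leftCov && rightCov)
    return(if (strand == "+") "full_dGGCCTGn" else "full_dGGCCTGr")
  if (leftCov && tractOv >= minTractBp)
    return(if (strand == "+") "5p_GGCCTGn" else "3p_GGCCTGn")
  if (rightCov && tractOv >= minTractBp)
    return(if (strand == "+") "3p_GGCCTGn" else "5p_GGCCTGn")
  "non_spanning"
}

## Core tokens of the locus fully contained in [fs, fe).
.fragCoreCount <- function(locus, fs, fe) {
  if (!length(locus@tokens)) return(NA_integer_)
  ends <- locus@repeatStart + cumsum(nchar(locus@tokens))
  starts <- ends - nchar(locus@tokens)
  sum(locus@tokens == locus@core & starts >= fs & ends <= fe)
}

## Per-base i.i.d. error injection; substitutions never reproduce the
## original base, insertions add one random base before the drawn position.
.injectErrors <- function(seq, rate, mix) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < rate)
  if (!length(hit)) return(seq)
  bases <- c("A", "C", "G", "T")
  type <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = mix)
  sub <- hit[type == "sub"]
  if (length(sub)) {
    shift <- sample(3L, length(sub), replace = TRUE)
    chars[sub] <- bases[(match(chars[sub], bases) - 1L + shift) %% 4L + 1L]
  }
  ins <- hit[type == "ins"]
  if (length(ins))
    chars[ins] <- paste0(sample(bases, length(ins), replace = TRUE),
                         chars[ins])
  del <- hit[type == "del"]
  if (length(del)) chars[del] <- ""
  paste(chars, collapse = "")
}

.drawReadLength <- function(model, locusLen) {
  len <- switch(model$type,
    fixed = if (is.null(model$length) || is.na(model$length))
      locusLen else model$length,
    lognormal = rlnorm(1, meanlog = model$meanlog, sdlog = model$sdlog),
    stop("unknown read length model type: ", model$type))
  minLen <- if (!is.null(model$min)) model$min else 500
  as.integer(max(1L, min(locusLen, max(minLen, round(len)))))
}

## Sample one fragment from a locus: truth is recorded before errors.
.oneFragment <- function(locus, readLength, errorRate, errorMix,
                         strandFraction, anchorK, maxEditFraction,
                         minTractBp) {
  L <- nchar(locus@locus)
  len <- .drawReadLength(readLength, L)
  fs <- sample.int(L - len + 1L, 1L) - 1L
  fe <- fs + len
  frag <- substr(locus@locus, fs + 1L, fe)
  strand <- if (runif(1) < strandFraction) "-" else "+"
  cls <- .truthClass(fs, fe, locus@repeatStart, locus@repeatEnd, strand,
                     anchorK, maxEditFraction, minTractBp)
  cc <- if (cls == "non_spanning") NA_integer_ else
    .fragCoreCount(locus, fs, fe)
  seq <- if (strand == "-") revComp(frag) else frag
  seq <- .injectErrors(seq, errorRate, errorMix)
  list(sequence = seq, strand = strand, true_class = cls,
       true_core_count = cc, frag_start = fs, frag_end = fe,
       true_fragment = frag)
}

.readsFromList <- function(frags, ids, errorRate, sampleId = NA_character_) {
  reads <- Biostrings::DNAStringSet(vapply(frags, `[[`, character(1),
                                           "sequence"))
  names(reads) <- ids
  S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
    sample_id = sampleId,
    strand = vapply(frags, `[[`, character(1), "strand"),
    true_class = vapply(frags, `[[`, character(1), "true_class"),
    true_core_count = vapply(frags, `[[`, integer(1), "true_core_count"),
    applied_error_rate = errorRate,
    frag_start = vapply(frags, `[[`, integer(1), "frag_start"),
    frag_end = vapply(frags, `[[`, integer(1), "frag_end"),
    true_fragment = vapply(frags, `[[`, character(1), "true_fragment"))
  reads
}

#' Simulate CLR-like noisy reads over one locus
#'
#' Fragments are sampled uniformly over the locus until the total sampled
#' bases reach `coverage * nchar(locus)`. Each fragment's truth span class
#' is recorded from its overlap with the repeat interval *before* error
#' injection; minus-strand reads are reverse-complemented, then per-base
#' i.i.d. substitution/insertion/deletion errors are applied at
#' `errorRate` split by `errorMix`. The defaults emulate PacBio CLR
#' character: a 12% total error rate inside the platform's 11--15% band,
#' with an indel-dominant mix.
#'
#' @param locus A [RepeatLocus-class].
#' @param coverage Fold coverage; > 0.
#' @param readLength Read length model: `list(type = "fixed", length =)`
#'   (NA means the full locus) or `list(type = "lognormal", meanlog =,
#'   sdlog =, min =)`, truncated to `[min, nchar(locus)]`.
#' @param errorRate Total per-base error rate in `[0, 0.5)`.
#' @param errorMix Named fractions `c(sub =, ins =, del =)` summing to 1.
#' @param strandFraction Fraction of reads sampled on the minus strand.
#' @param anchorK,maxEditFraction,minTractBp Classifier geometry used to
#'   record truth span classes (see [classifyReads()]).
#' @param seed Integer seed; output is deterministic given it.
#' @param idPrefix Prefix for read ids.
#' @return A [Biostrings::DNAStringSet] with per-read truth in `mcols()`:
#'   strand, true span class, true core count (complete core units of the
#'   fragment, NA for non-spanning reads), the applied error rate, and the
#'   pre-error fragment and its coordinates.
#' @examples
#' fl <- randomFlanks(60, seed = 1)
#' loc <- generateLocus(generateAllele(20, seed = 2), fl$left, fl$right)
#' rd <- simulateReads(loc, coverage = 3, errorRate = 0, seed = 3)
#' truthTable(rd)[1:3, ]
#' @export
simulateReads <- function(locus, coverage = 100,
                          readLength = list(type = "lognormal",
                                            meanlog = log(5000),
                                            sdlog = 0.5, min = 500),
                          errorRate = 0.12,
                          errorMix = c(sub = 0.25, ins = 0.45, del = 0.30),
                          strandFraction = 0.5, anchorK = 30,
                          maxEditFraction = 0.25, minTractBp = 1,
                          seed = NULL, idPrefix = "sim") {
  if (coverage <= 0) stop("'coverage' must be > 0")
  if (errorRate < 0 || errorRate >= 0.5)
    stop("'errorRate' must lie in [0, 0.5)")
  if (abs(sum(errorMix) - 1) > 1e-6 || any(errorMix < 0))
    stop("'errorMix' must be non-negative fractions summing to 1")
  if (strandFraction < 0 || strandFraction > 1)
    stop("'strandFraction' must lie in [0, 1]")
  L <- nchar(locus@locus)
  withSeed(seed, {
    frags <- list()
    total <- 0
    while (total < coverage * L) {
      fr <- .oneFragment(locus, readLength, errorRate, errorMix,
                         strandFraction, anchorK, maxEditFraction,
                         minTractBp)
      frags[[length(frags) + 1L]] <- fr
      total <- total + (fr$frag_end - fr$frag_start)
    }
    ids <- sprintf("%s_read_%05d", idPrefix, seq_along(frags))
    .readsFromList(frags, ids, errorRate)
  })
}

#' Simulate one sample with per-read repeat-number jitter
#'
#' Emulates the somatic heterogeneity seen in expansion carriers: every
#' read is drawn from a fresh allele whose core repeat count is jittered
#' around `meanCore` (normal, sd `jitterSd`), then one fragment is sampled
#' from that read's own locus. Jitter is a simulation feature describing
#' read-to-read spread, not a claim about its mechanism.
#'
#' @param sampleId Sample label carried into `mcols()` and reports.
#' @param meanCore Mean true core repeat count of the sample.
#' @param jitterSd Standard deviation of the per-read core count.
#' @param interruptionFraction,variantWeights,catalog Passed to
#'   [generateAllele()].
#' @param leftFlank,rightFlank Flank sequences shared by all reads.
#' @param coverage Fold coverage relative to the sample's mean locus
#'   length.
#' @inheritParams simulateReads
#' @return A [Biostrings::DNAStringSet] with truth `mcols()` as in
#'   [simulateReads()].
#' @export
simulateSample <- function(sampleId, meanCore, jitterSd = 50,
                           interruptionFraction = 0.05,
                           variantWeights = NULL,
                           catalog = MotifCatalog(),
                           leftFlank, rightFlank, coverage = 40,
                           readLength = list(type = "lognormal",
                                             meanlog = log(5000),
                                             sdlog = 0.5, min = 500),
                           errorRate = 0.12,
                           errorMix = c(sub = 0.25, ins = 0.45,
                                        del = 0.30),
                           strandFraction = 0.5, anchorK = 30,
                           maxEditFraction = 0.25, minTractBp = 1,
                           seed = NULL) {
  if (coverage <= 0) stop("'coverage' must be > 0")
  if (jitterSd < 0) stop("'jitterSd' must be >= 0")
  nominalLen <- nchar(leftFlank) + nchar(rightFlank) +
    round(meanCore / (1 - interruptionFraction)) * nchar(coreMotif(catalog))
  withSeed(seed, {
    frags <- list()
    total <- 0
    while (total < coverage * nominalLen) {
      cc <- max(1, round(rnorm(1, meanCore, jitterSd)))
      allele <- generateAllele(cc, interruptionFraction, catalog,
                               variantWeights)
      loc <- generateLocus(allele, leftFlank, rightFlank, anchorK)
      fr <- .oneFragment(loc, readLength, errorRate, errorMix,
                         strandFraction, anchorK, maxEditFraction,
                         minTractBp)
      frags[[length(frags) + 1L]] <- fr
      total <- total + (fr$frag_end - fr$frag_start)
    }
    ids <- sprintf("%s_read_%05d", sampleId, seq_along(frags))
    .readsFromList(frags, ids, errorRate, sampleId = sampleId)
  })
}

#' Truth table of a simulated read set
#'
#' @param reads Simulated reads from [simulateReads()] or
#'   [simulateSample()].
#' @return `data.frame` with read_id, strand, true_class, true_core_count.
#' @export
truthTable <- function(reads) {
  mc <- S4Vectors::mcols(reads)
  data.frame(read_id = names(reads), strand = mc$strand,
             true_class = mc$true_class,
             true_core_count = mc$true_core_count,
             stringsAsFactors = FALSE)
}

#' Write the simulator truth as TSV
#'
#' @inheritParams truthTable
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTruthTsv <- function(reads, path) {
  write.table(truthTable(reads), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a locus as FASTA
#'
#' The header carries the repeat interval as `repeat=<start>-<end>`
#' (0-based half-open).
#'
#' @param locus A [RepeatLocus-class].
#' @param path Output file.
#' @param name Sequence name.
#' @return `path`, invisibly.
#' @export
writeLocusFasta <- function(locus, path, name = "locus") {
  writeFastaOne(locus@locus, path,
                sprintf("%s repeat=%d-%d", name, locus@repeatStart,
                        locus@repeatEnd))
  invisible(path)
}
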