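#' ReferencePair: native and expanded ("fake") reference sequences
#'
#' Alignment-based discovery of expansion-spanning reads uses a pair of
#' references: the native locus, whose tract holds only the short normal
#' run of core motifs, and an expanded copy in which a long run of core
#' motifs is inserted *before* the native run (default 1000 units before
#' the native 4). Reads carrying a pathogenic expansion align across the
#' repeat only on the expanded copy.
#'
#' @slot native,fake Full reference sequences.
#' @slot nNative,nInsert Native and inserted core-unit counts.
#' @slot core Core motif.
#' @slot nativeStart,nativeEnd,fakeStart,fakeEnd 0-based half-open repeat
#'   intervals of the two references.
#'
#' @seealso [buildReferencePair()]
#' @name ReferencePair-class
#' @exportClass ReferencePair
setClass("ReferencePair",
  representation(native = "character", fake = "character",
                 nNative = "integer", nInsert = "integer",
                 core = "character", nativeStart = "integer",
                 nativeEnd = "integer", fakeStart = "integer",
                 fakeEnd = "integer"))

setValidity("ReferencePair", function(object) {
  msg <- character(0)
  k <- nchar(object@core)
  if (nchar(object@fake) - nchar(object@native) != object@nInsert * k)
    msg <- c(msg, "len(fake) - len(native) must equal nInsert * len(core)")
  if (object@fakeEnd - object@fakeStart !=
      (object@nInsert + object@nNative) * k)
    msg <- c(msg, "fake interval length must be (nInsert + nNative) * len(core)")
  nativeTract <- substr(object@native, object@nativeStart + 1L,
                        object@nativeEnd)
  fakeTract <- substr(object@fake, object@fakeStart + 1L, object@fakeEnd)
  if (!identical(substring(fakeTract,
                           nchar(fakeTract) - nchar(nativeTract) + 1L),
                 nativeTract))
    msg <- c(msg, "native tract must be a suffix of the fake tract")
  if (length(msg)) msg else TRUE
})

#' Build the native/expanded reference pair
#'
#' @param leftFlank,rightFlank Flank sequences (same rules as
#'   [generateLocus()]).
#' @param core Core motif (uppercase A/C/G/T).
#' @param nNative Core units in the native reference (default 4).
#' @param nInsert Core units inserted before the native run in the
#'   expanded reference (default 1000).
#' @param anchorK Minimum flank length (default 30).
#' @return A [ReferencePair-class].
#' @examples
#' fl <- randomFlanks(50, seed = 1)
#' rp <- buildReferencePair(fl$left, fl$right)
#' nchar(fakeRef(rp)) - nchar(nativeRef(rp))  # 6000
#' @export
buildReferencePair <- function(leftFlank, rightFlank, core = "GGCCTG",
                               nNative = 4, nInsert = 1000, anchorK = 30) {
  assertDna(core, "core")
  assertDna(leftFlank, "leftFlank")
  assertDna(rightFlank, "rightFlank")
  if (nNative < 0) stop("'nNative' must be >= 0")
  if (nInsert < 1) stop("'nInsert' must be >= 1")
  run2 <- strrep(core, 2)
  for (fl in c(leftFlank, rightFlank)) {
    if (nchar(fl) < anchorK) stop("flanks must be at least ", anchorK, " bp")
    if (grepl(run2, fl, fixed = TRUE))
      stop("flank contains a run of >= 2 core motifs")
  }
  k <- nchar(core)
  lf <- nchar(leftFlank)
  new("ReferencePair",
      native = paste0(leftFlank, strrep(core, nNative), rightFlank),
      fake = paste0(leftFlank, strrep(core, nInsert + nNative), rightFlank),
      nNative = as.integer(nNative), nInsert = as.integer(nInsert),
      core = core,
      nativeStart = as.integer(lf), nativeEnd = as.integer(lf + nNative * k),
      fakeStart = as.integer(lf),
      fakeEnd = as.integer(lf + (nInsert + nNative) * k))
}

#' @describeIn ReferencePair-class Native reference sequence.
#' @param x A `ReferencePair`.
#' @export
setGeneric("nativeRef", function(x) standardGeneric("nativeRef"))

#' @rdname ReferencePair-class
#' @export
setMethod("nativeRef", "ReferencePair", function(x) x@native)

#' @describeIn ReferencePair-class Expanded ("fake") reference sequence.
#' @export
setGeneric("fakeRef", function(x) standardGeneric("fakeRef"))

#' @rdname ReferencePair-class
#' @export
setMethod("fakeRef", "ReferencePair", function(x) x@fake)

#' @describeIn ReferencePair-class Repeat intervals of both references as a
#'   data.frame (0-based half-open).
#' @export
setGeneric("refIntervals", function(x) standardGeneric("refIntervals"))

#' @rdname ReferencePair-class
#' @export
setMethod("refIntervals", "ReferencePair", function(x) {
  data.frame(reference = c("native", "fake"),
             start = c(x@nativeStart, x@fakeStart),
             end = c(x@nativeEnd, x@fakeEnd))
})

setMethod("show", "ReferencePair", function(object) {
  cat("ReferencePair (core ", object@core, ")\n", sep = "")
  cat("  native: ", nchar(object@native), " bp, ", object@nNative,
      " core units\n", sep = "")
  cat("  fake:   ", nchar(object@fake), " bp, ", object@nInsert, " + ",
      object@nNative, " core units\n", sep = "")
})

#' Write a reference pair as FASTA plus BED sidecars
#'
#' Writes `native.fa`/`fake.fa` (headers carry `repeat=<start>-<end>`) and
#' 3-column BED files with the 0-based half-open repeat intervals.
#'
#' @param pair A [ReferencePair-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
writeReferencePair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(native_fa = file.path(dir, "native.fa"),
             fake_fa = file.path(dir, "fake.fa"),
             native_bed = file.path(dir, "native.bed"),
             fake_bed = file.path(dir, "fake.bed"))
  writeFastaOne(pair@native, paths[["native_fa"]],
                sprintf("native repeat=%d-%d", pair@nativeStart,
                        pair@nativeEnd))
  writeFastaOne(pair@fake, paths[["fake_fa"]],
                sprintf("fake repeat=%d-%d", pair@fakeStart, pair@fakeEnd))
  writeLines(sprintf("native\t%d\t%d", pair@nativeStart, pair@nativeEnd),
             paths[["native_bed"]])
  writeLines(sprintf("fake\t%d\t%d", pair@fakeStart, pair@fakeEnd),
             paths[["fake_bed"]])
  invisible(paths)
}
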