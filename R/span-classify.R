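#' Flank anchors for spanning-read discovery
#'
#' The anchors are the innermost `anchorK` bp of each flank: the suffix of
#' the left flank and the prefix of the right flank, i.e. the sequences
#' immediately bordering the repeat tract.
#'
#' @param leftFlank,rightFlank Flank sequences.
#' @param anchorK Anchor length (default 30 bp).
#' @return `list(left =, right =)` anchor sequences.
#' @export
flankAnchors <- function(leftFlank, rightFlank, anchorK = 30) {
  if (nchar(leftFlank) < anchorK || nchar(rightFlank) < anchorK)
    stop("flanks must be at least ", anchorK, " bp")
  list(left = substring(leftFlank, nchar(leftFlank) - anchorK + 1L),
       right = substring(rightFlank, 1L, anchorK))
}

#' Locate flank anchors on a read by semi-global alignment
#'
#' Each anchor is aligned end-to-end against the best-matching infix of
#' the read and of its reverse complement (unit edit costs). A hit is
#' reported iff its edit distance is at most
#' `ceiling(maxEditFraction * nchar(anchor))`; at most one hit per
#' (anchor, strand) is kept -- the minimum-distance one, ties broken by
#' leftmost read start. Minus-strand hit coordinates are given on the
#' reverse-complemented read.
#'
#' @param read Read sequence (character).
#' @param leftAnchor,rightAnchor Anchor sequences, e.g. from
#'   [flankAnchors()].
#' @param maxEditFraction Maximum tolerated edit distance as a fraction of
#'   the anchor length, in `[0, 0.5)`. The default 0.25 tolerates the
#'   11--15% CLR error rate affecting both anchor bases and read bases.
#' @return `data.frame` with columns which (`"left"`/`"right"`), strand,
#'   read_start, read_end (0-based half-open), edit_distance; zero rows
#'   when nothing matches (an anchor longer than the read is no hit, not
#'   an error).
#' @export
findAnchors <- function(read, leftAnchor, rightAnchor,
                        maxEditFraction = 0.25) {
  if (maxEditFraction < 0 || maxEditFraction >= 0.5)
    stop("'maxEditFraction' must lie in [0, 0.5)")
  read <- as.character(read)
  rc <- revComp(read)
  anchors <- list(left = leftAnchor, right = rightAnchor)
  out <- list()
  for (which in names(anchors)) {
    anc <- anchors[[which]]
    maxEd <- as.integer(ceiling(maxEditFraction * nchar(anc)))
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") read else rc
      if (nchar(anc) > nchar(subj)) next
      hit <- .cppInfixAlign(subj, anc)
      if (hit[["distance"]] <= maxEd)
        out[[length(out) + 1L]] <- data.frame(
          which = which, strand = strand,
          read_start = hit[["start"]], read_end = hit[["end"]],
          edit_distance = hit[["distance"]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(which = character(0), strand = character(0),
                      read_start = integer(0), read_end = integer(0),
                      edit_distance = integer(0)))
  do.call(rbind, out)
}

## Resolve anchor hits into a span class plus the hits used.
## Returns list(span_class, left = row-or-NULL, right = row-or-NULL).
.resolveHits <- function(hits, readLength, minTractBp = 1) {
  pick <- function(which, strand) {
    i <- hits$which == which & hits$strand == strand
    if (any(i)) hits[which(i)[1L], , drop = FALSE] else NULL
  }
  for (strand in c("+", "-")) {
    l <- pick("left", strand); r <- pick("right", strand)
    if (!is.null(l) && !is.null(r)) {
      if (l$read_end > r$read_start) {
        warning("contradictory anchor hits (left right of right); ",
                "read classified non-spanning")
        return(list(span_class = "non_spanning", left = NULL, right = NULL))
      }
      cls <- if (strand == "+") "full_dGGCCTGn" else "full_dGGCCTGr"
      return(list(span_class = cls, left = l, right = r))
    }
  }
  ## partial candidates: hit, its class, and the bases on the tract side
  cand <- list()
  addCand <- function(row, cls, beyond) {
    if (!is.null(row) && beyond >= minTractBp)
      cand[[length(cand) + 1L]] <<- list(row = row, cls = cls,
                                         beyond = beyond)
  }
  l <- pick("left", "+")
  if (!is.null(l)) addCand(l, "5p_GGCCTGn", readLength - l$read_end)
  r <- pick("right", "-")
  if (!is.null(r)) addCand(r, "5p_GGCCTGn", r$read_start)
  r <- pick("right", "+")
  if (!is.null(r)) addCand(r, "3p_GGCCTGn", r$read_start)
  l <- pick("left", "-")
  if (!is.null(l)) addCand(l, "3p_GGCCTGn", readLength - l$read_end)
  if (!length(cand))
    return(list(span_class = "non_spanning", left = NULL, right = NULL))
  ## strand-involution-symmetric ordering: distance, then tract-side length
  ord <- order(vapply(cand, function(c) c$row$edit_distance, numeric(1)),
               -vapply(cand, function(c) c$beyond, numeric(1)),
               vapply(cand, function(c) c$cls, character(1)))
  best <- cand[[ord[1L]]]
  out <- list(span_class = best$cls, left = NULL, right = NULL)
  out[[best$row$which]] <- best$row
  out
}

#' Classify a read's span class from its anchor hits
#'
#' Both anchors on the plus orientation give a forward full-spanning read
#' (`full_dGGCCTGn`); both on the reverse-complemented read give
#' `full_dGGCCTGr`. A single left(+) or right(-) hit with at least
#' `minTractBp` read bases on the tract side is 5'-partial
#' (`5p_GGCCTGn`); a single right(+) or left(-) hit likewise is
#' 3'-partial. Everything else -- including contradictory hits, which
#' raise a warning -- is `non_spanning`.
#'
#' @param hits Hit table from [findAnchors()].
#' @param readLength Length of the read in bp.
#' @param minTractBp Minimum bases beyond the anchor for a partial call;
#'   default 1 (any overhang into the tract counts).
#' @return A span class string.
#' @export
classifyRead <- function(hits, readLength, minTractBp = 1) {
  .resolveHits(hits, readLength, minTractBp)$span_class
}

#' Extract the repeat tract from a classified read
#'
#' For full-spanning reads, the read segment strictly between the inner
#' ends of the two anchors; for partial reads, the segment from the single
#' anchor's inner end to the read end. Reverse-orientation reads are
#' reverse-complemented first, so every tract is reported 5' to 3' on the
#' repeat's plus convention.
#'
#' @param read Read sequence (character).
#' @param hits Hit table from [findAnchors()].
#' @param spanClass Class from [classifyRead()] (re-derived internally for
#'   consistency).
#' @param minTractBp As in [classifyRead()].
#' @return The tract as a character string (`NA` for non-spanning reads;
#'   a negative-length segment yields an empty tract with a warning).
#' @export
extractTract <- function(read, hits, spanClass = NULL, minTractBp = 1) {
  read <- as.character(read)
  res <- .resolveHits(hits, nchar(read), minTractBp)
  if (!is.null(spanClass) && !identical(spanClass, res$span_class))
    warning("'spanClass' disagrees with hit resolution; using hits")
  if (res$span_class == "non_spanning") return(NA_character_)
  minus <- if (!is.null(res$left)) res$left$strand == "-" else
    res$right$strand == "-"
  oriented <- if (minus) revComp(read) else read
  from <- if (!is.null(res$left)) res$left$read_end else 0L
  to <- if (!is.null(res$right)) res$right$read_start else nchar(oriented)
  if (to < from) {
    warning("negative-length tract segment; returning empty tract")
    return("")
  }
  substr(oriented, from + 1L, to)
}

#' Classify a set of reads against a repeat locus
#'
#' Runs [findAnchors()], [classifyRead()] and [extractTract()] over a read
#' set using the innermost `anchorK` bp of each flank as anchors.
#'
#' @param reads A [Biostrings::DNAStringSet] or named character vector.
#' @param leftFlank,rightFlank Locus flank sequences.
#' @param anchorK Anchor length (default 30 bp).
#' @param maxEditFraction Per-anchor edit tolerance (see [findAnchors()]).
#' @param minTractBp Minimum overhang for partial calls.
#' @param sampleId Optional sample label column.
#' @return `data.frame` with one row per read: read_id, sample_id,
#'   span_class, strand (of the repeat-spanning alignment; NA for
#'   non-spanning), tract, tract_length, and the used anchor coordinates
#'   (0-based half-open, on the oriented read) with edit distances.
#' @examples
#' fl <- randomFlanks(60, seed = 1)
#' loc <- generateLocus(generateAllele(30, seed = 2), fl$left, fl$right)
#' rd <- simulateReads(loc, coverage = 2, errorRate = 0, seed = 3)
#' table(classifyReads(rd, fl$left, fl$right)$span_class)
#' @export
classifyReads <- function(reads, leftFlank, rightFlank, anchorK = 30,
                          maxEditFraction = 0.25, minTractBp = 1,
                          sampleId = NA_character_) {
  anchors <- flankAnchors(leftFlank, rightFlank, anchorK)
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    hits <- findAnchors(seqs[i], anchors$left, anchors$right,
                        maxEditFraction)
    res <- .resolveHits(hits, nchar(seqs[i]), minTractBp)
    tractSeq <- if (res$span_class == "non_spanning") NA_character_ else
      extractTract(seqs[i], hits, minTractBp = minTractBp)
    strand <- if (res$span_class == "non_spanning") NA_character_ else
      if (!is.null(res$left)) res$left$strand else res$right$strand
    grab <- function(h, f) if (is.null(h)) NA_integer_ else h[[f]]
    data.frame(read_id = ids[i], sample_id = sampleId,
               span_class = res$span_class, strand = strand,
               tract = tractSeq,
               tract_length = ifelse(is.na(tractSeq), NA_integer_,
                                     nchar(tractSeq)),
               left_start = grab(res$left, "read_start"),
               left_end = grab(res$left, "read_end"),
               left_edit = grab(res$left, "edit_distance"),
               right_start = grab(res$right, "read_start"),
               right_end = grab(res$right, "read_end"),
               right_edit = grab(res$right, "edit_distance"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write classified reads as TSV (and tracts as FASTA)
#'
#' @param classified Output of [classifyReads()].
#' @param path Output TSV; tract sequences are omitted (use
#'   [writeTractFasta()]).
#' @return `path`, invisibly.
#' @export
writeClassifiedTsv <- function(classified, path) {
  write.table(classified[, setdiff(names(classified), "tract")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClassifiedTsv
#' @export
writeTractFasta <- function(classified, path) {
  sp <- classified[!is.na(classified$tract) & nzchar(classified$tract), ]
  lines <- unlist(lapply(seq_len(nrow(sp)), function(i) {
    c(paste0(">", sp$read_id[i], " class=", sp$span_class[i]),
      gsub("(.{80})", "\\1\n", sp$tract[i], perl = TRUE))
  }))
  writeLines(lines %||% character(0), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
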