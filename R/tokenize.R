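#' TokenizedTract: a tract tiled into motif tokens
#'
#' Result of the dynamic-programming tokenization of a repeat tract: an
#' ordered set of labelled intervals that tile the tract exactly. Bases no
#' catalog motif explains within the cost cap carry the label `"other"`
#' (adjacent such bases are merged into runs).
#'
#' @slot tract The tokenized sequence.
#' @slot tokens `data.frame` with label, start, end (0-based half-open on
#'   the tract) and cost per token.
#' @slot totalCost Total edit cost of the optimal tiling.
#' @slot unassigned Number of `"other"`-labelled bases.
#'
#' @seealso [tokenize()], [motifRatios()]
#' @name TokenizedTract-class
#' @exportClass TokenizedTract
setClass("TokenizedTract",
  representation(tract = "character", tokens = "data.frame",
                 totalCost = "integer", unassigned = "integer"))

setValidity("TokenizedTract", function(object) {
  tk <- object@tokens
  msg <- character(0)
  if (nrow(tk)) {
    if (tk$start[1L] != 0L || tk$end[nrow(tk)] != nchar(object@tract) ||
        (nrow(tk) > 1L && any(tk$start[-1L] != tk$end[-nrow(tk)])))
      msg <- c(msg, "tokens must tile the tract exactly")
  } else if (nzchar(object@tract)) {
    msg <- c(msg, "non-empty tract without tokens")
  }
  if (length(msg)) msg else TRUE
})

#' Tokenize a repeat tract into catalog motifs
#'
#' Minimum-cost tiling by dynamic programming: from each position a step
#' consumes `unitMin`--`unitMax` bases at the edit distance of the
#' best-fitting catalog motif (steps costing more than `maxUnitCost` are
#' inadmissible), or falls back to a single `"other"` base at cost 1.
#' Among equal-cost tilings the walk prefers catalog steps over fallback,
#' the core label, then the longer unit, then the lexicographically
#' smaller label -- a fixed order, so results are stable across runs. On
#' an exact concatenation of catalog motifs the tiling has cost 0 and
#' recovers the generating tokens whenever they are unambiguous.
#'
#' @param tractSeq Non-empty tract sequence (uppercase A/C/G/T).
#' @param catalog A [MotifCatalog-class].
#' @param unitMin,unitMax Unit-size bounds (defaults 4 and 8, covering the
#'   observed 5--7 nt motifs with margin).
#' @param maxUnitCost Maximum edit cost a single token may absorb
#'   (default 2).
#' @return A [TokenizedTract-class].
#' @examples
#' tok <- tokenize(strrep("GGCCTG", 3), MotifCatalog())
#' tokenTable(tok)
#' @export
tokenize <- function(tractSeq, catalog = MotifCatalog(), unitMin = 4,
                     unitMax = 8, maxUnitCost = 2) {
  assertDna(tractSeq, "tractSeq")
  res <- .cppTokenize(tractSeq, catalogMotifs(catalog),
                      as.integer(unitMin), as.integer(unitMax),
                      as.integer(maxUnitCost))
  tk <- data.frame(label = res$label, start = res$start, end = res$end,
                   cost = res$cost, stringsAsFactors = FALSE)
  ## merge runs of single-base "other" fallbacks
  if (nrow(tk) > 1L) {
    run <- cumsum(!(tk$label == "other" &
                      c(FALSE, tk$label[-nrow(tk)] == "other")))
    tk <- do.call(rbind, lapply(split(tk, run), function(g) {
      data.frame(label = g$label[1L], start = g$start[1L],
                 end = g$end[nrow(g)], cost = sum(g$cost),
                 stringsAsFactors = FALSE)
    }))
    rownames(tk) <- NULL
  }
  new("TokenizedTract", tract = tractSeq, tokens = tk,
      totalCost = as.integer(res$total_cost),
      unassigned = as.integer(sum((tk$end - tk$start)[tk$label ==
                                                        "other"])))
}

#' @describeIn TokenizedTract-class Token table (label, start, end, cost).
#' @param x A `TokenizedTract`.
#' @export
setGeneric("tokenTable", function(x) standardGeneric("tokenTable"))

#' @rdname TokenizedTract-class
#' @export
setMethod("tokenTable", "TokenizedTract", function(x) x@tokens)

#' @describeIn TokenizedTract-class Ordered token labels.
#' @export
setGeneric("tokenLabels", function(x) standardGeneric("tokenLabels"))

#' @rdname TokenizedTract-class
#' @export
setMethod("tokenLabels", "TokenizedTract", function(x) x@tokens$label)

#' @describeIn TokenizedTract-class Total cost of the optimal tiling.
#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))

#' @rdname TokenizedTract-class
#' @export
setMethod("totalCost", "TokenizedTract", function(x) x@totalCost)

#' @describeIn TokenizedTract-class Number of unassigned ("other") bases.
#' @export
setGeneric("unassignedBases", function(x) standardGeneric("unassignedBases"))

#' @rdname TokenizedTract-class
#' @export
setMethod("unassignedBases", "TokenizedTract", function(x) x@unassigned)

setMethod("show", "TokenizedTract", function(object) {
  cat("TokenizedTract:", nchar(object@tract), "bp,",
      nrow(object@tokens), "tokens, cost", object@totalCost, "\n")
  print(head(table(object@tokens$label), 10))
})

## Promote recurring unexplained segments to literal motif labels: an
## "other" run of 4--8 bp whose exact sequence recurs at least minRecur
## times across the tract set is reported under its own sequence label.
.promoteNovel <- function(tokenList, minRecur = 3, range = c(4L, 8L)) {
  segs <- lapply(tokenList, function(tok) {
    tk <- tok@tokens
    i <- tk$label == "other" & (tk$end - tk$start) >= range[1L] &
      (tk$end - tk$start) <= range[2L]
    if (!any(i)) return(character(0))
    substring(tok@tract, tk$start[i] + 1L, tk$end[i])
  })
  tab <- table(unlist(segs))
  keep <- names(tab)[tab >= minRecur]
  if (!length(keep)) return(tokenList)
  lapply(tokenList, function(tok) {
    tk <- tok@tokens
    w <- tk$end - tk$start
    seg <- substring(tok@tract, tk$start + 1L, tk$end)
    i <- tk$label == "other" & seg %in% keep
    tk$label[i] <- seg[i]
    tok@tokens <- tk
    tok@unassigned <- as.integer(sum(w[tk$label == "other"]))
    tok
  })
}

#' Per-motif nucleotide ratios over tokenized tracts
#'
#' The ratio of a motif is the percentage of tract nucleotides its tokens
#' cover, over the pooled nucleotides of all supplied tracts (scope
#' `"pooled"`, the default) or per tract (`"per_tract"`, returning a list
#' of tables). Besides the overall table (`group == "all"`), per-length
#' groups (5/6/7 nt) are re-normalized within the group.
#'
#' @param tokenized A [TokenizedTract-class] or list of them.
#' @param scope `"pooled"` or `"per_tract"`.
#' @param promoteNovel Report unexplained 4--8 bp segments recurring at
#'   least `minRecur` times under their literal sequence label.
#' @param minRecur Recurrence threshold for novel-motif promotion.
#' @return `data.frame` with label, length_nt (NA for `"other"`),
#'   nucleotides, percent and group; the `"all"` rows sum to 100.
#' @examples
#' tok <- tokenize(paste0("GGCCTG", "GGCTG"), MotifCatalog())
#' motifRatios(tok)
#' @export
motifRatios <- function(tokenized, scope = c("pooled", "per_tract"),
                        promoteNovel = TRUE, minRecur = 3) {
  scope <- match.arg(scope)
  if (is(tokenized, "TokenizedTract")) tokenized <- list(tokenized)
  if (!length(tokenized)) stop("need at least one tokenized tract")
  if (promoteNovel) tokenized <- .promoteNovel(tokenized, minRecur)
  if (scope == "per_tract")
    return(lapply(tokenized, function(t)
      .ratioTable(list(t))))
  .ratioTable(tokenized)
}

.ratioTable <- function(tokenList) {
  lab <- unlist(lapply(tokenList, function(t) t@tokens$label))
  wid <- unlist(lapply(tokenList,
                       function(t) t@tokens$end - t@tokens$start))
  nt <- tapply(wid, lab, sum)
  total <- sum(nt)
  all <- data.frame(label = names(nt),
                    length_nt = ifelse(names(nt) == "other", NA_integer_,
                                       nchar(names(nt))),
                    nucleotides = as.integer(nt),
                    percent = 100 * as.numeric(nt) / total,
                    group = "all", stringsAsFactors = FALSE)
  all <- all[order(-all$percent, all$label), ]
  groups <- lapply(c(5L, 6L, 7L), function(len) {
    g <- all[!is.na(all$length_nt) & all$length_nt == len, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    g$percent <- 100 * g$nucleotides / sum(g$nucleotides)
    g$group <- paste0(len, "nt")
    g
  })
  out <- rbind(all, do.call(rbind, groups))
  rownames(out) <- NULL
  attr(out, "total_nt") <- total
  out
}

#' Top motifs by nucleotide ratio
#'
#' @param table Ratio table from [motifRatios()].
#' @param k Number of labels to return.
#' @param lengthFilter `NULL` for the overall ranking, or one of 5, 6, 7
#'   to rank only motifs of that length.
#' @return Label character vector, highest ratio first (ties broken
#'   lexicographically).
#' @export
topMotifs <- function(table, k = 10, lengthFilter = NULL) {
  g <- if (is.null(lengthFilter)) table[table$group == "all", ] else
    table[table$group == paste0(lengthFilter, "nt"), ]
  if (!nrow(g)) return(character(0))
  g <- g[order(-g$percent, g$label), ]
  head(g$label, k)
}

#' Motifs rarer than a percentage threshold
#'
#' Labels whose overall nucleotide ratio is strictly below `thresholdPct`
#' (default 1%); these are blacked out in waterfall schematics.
#'
#' @inheritParams topMotifs
#' @param thresholdPct Strict percentage threshold.
#' @return Character vector of rare labels.
#' @export
rareMotifLabels <- function(table, thresholdPct = 1.0) {
  g <- table[table$group == "all", ]
  g$label[g$percent < thresholdPct]
}

#' Write motif tokens / ratio tables as TSV
#'
#' @param tokenized A [TokenizedTract-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeTokensTsv <- function(tokenized, path) {
  write.table(tokenTable(tokenized), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTokensTsv
#' @param table Ratio table from [motifRatios()].
#' @export
writeMotifRatiosTsv <- function(table, path) {
  out <- table
  out$percent <- sprintf("%.4f", out$percent)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
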