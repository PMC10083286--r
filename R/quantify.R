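#' Count core repeats in a tract
#'
#' The default (`mode = "dp"`) counts tokens labelled with the core motif
#' in the minimum-cost tokenization of the tract (see [tokenize()]), so
#' sequencing errors inside a unit degrade the count gracefully. For
#' tracts that are exact concatenations of catalog motifs this equals the
#' number of core units. `mode = "exact"` instead counts non-overlapping
#' exact occurrences of the core motif, left-greedy, for comparison.
#'
#' @param tractSeq Tract sequence; may be empty (count 0).
#' @param catalog A [MotifCatalog-class].
#' @param mode `"dp"` (tokenizer-based, default) or `"exact"`.
#' @param ... Passed to [tokenize()] in `"dp"` mode.
#' @return Integer core repeat count.
#' @examples
#' countCoreRepeats(strrep("GGCCTG", 4))  # 4
#' @export
countCoreRepeats <- function(tractSeq, catalog = MotifCatalog(),
                             mode = c("dp", "exact"), ...) {
  mode <- match.arg(mode)
  if (is.na(tractSeq)) return(NA_integer_)
  assertDna(tractSeq, "tractSeq", allowEmpty = TRUE)
  if (!nzchar(tractSeq)) return(0L)
  if (mode == "exact") {
    m <- gregexpr(coreMotif(catalog), tractSeq, fixed = TRUE)[[1L]]
    return(if (m[1L] == -1L) 0L else length(m))
  }
  tok <- tokenize(tractSeq, catalog, ...)
  sum(tokenLabels(tok) == coreMotif(catalog))
}

#' Pathogenic repeat-count test
#'
#' A repeat number is pathogenic iff it is strictly greater than the
#' threshold; 650 is the lower bound of expanded SCA36 alleles, so a count
#' of exactly 650 is not called pathogenic.
#'
#' @param coreCount Non-negative repeat count(s).
#' @param threshold Pathogenic threshold (default 650).
#' @return Logical vector.
#' @examples
#' isPathogenic(c(650, 651, 746))
#' @export
isPathogenic <- function(coreCount, threshold = 650) {
  if (any(coreCount < 0, na.rm = TRUE)) stop("'coreCount' must be >= 0")
  coreCount > threshold
}

#' Ratio of pathogenic subreads, as reported
#'
#' `100 * n650 / subreads`, rounded half-up to two decimals -- the
#' convention of the per-sample report (e.g. 9 of 76 spanning subreads
#' gives 11.84).
#'
#' @param n650 Subreads with core repeat count above the threshold.
#' @param subreads Total spanning subreads.
#' @return Percentage rounded to 2 decimals (0 when `subreads` is 0).
#' @examples
#' pathogenicRatio(9, 76)    # 11.84
#' pathogenicRatio(23, 162)  # 14.20
#' @export
pathogenicRatio <- function(n650, subreads) {
  if (subreads == 0) return(0)
  roundHalfUp(100 * n650 / subreads, 2)
}

#' Per-sample repeat summary (spanning-subread statistics)
#'
#' One row of the per-sample report: total spanning subreads (full + both
#' partial classes + reverse full), the number and ratio of subreads whose
#' core repeat count exceeds the pathogenic threshold (the ratio's
#' denominator is all spanning subreads), the full-length subread count,
#' and min/mean/max tract length and core repeat number over full-length
#' tracts only (means reported to the nearest integer).
#'
#' @param classified Output of [classifyReads()], or any `data.frame` with
#'   `span_class` and `tract` columns.
#' @param sampleId Sample label.
#' @param catalog A [MotifCatalog-class].
#' @param threshold Pathogenic threshold (default 650).
#' @param countMode Passed to [countCoreRepeats()].
#' @return One-row `data.frame` with columns sample_id, subread_number,
#'   n_650plus, ratio_650plus, full_count, max/mean/min_length_bp,
#'   max/mean/min_repeats, plus full_fwd/full_rev detail columns. A sample
#'   with zero spanning reads yields zeros (ratio 0) with a warning.
#' @export
summarizeSample <- function(classified, sampleId = "sample",
                            catalog = MotifCatalog(), threshold = 650,
                            countMode = "dp") {
  sp <- classified[classified$span_class != "non_spanning" &
                     !is.na(classified$tract), , drop = FALSE]
  if (!nrow(sp)) {
    warning("no spanning reads for sample ", sampleId,
            "; reporting zeros")
    return(data.frame(sample_id = sampleId, subread_number = 0L,
                      n_650plus = 0L, ratio_650plus = 0,
                      full_count = 0L, max_length_bp = NA_integer_,
                      mean_length_bp = NA_integer_,
                      min_length_bp = NA_integer_,
                      max_repeats = NA_integer_, mean_repeats = NA_integer_,
                      min_repeats = NA_integer_, full_fwd = 0L,
                      full_rev = 0L, stringsAsFactors = FALSE))
  }
  counts <- vapply(sp$tract, countCoreRepeats, integer(1),
                   catalog = catalog, mode = countMode, USE.NAMES = FALSE)
  full <- sp$span_class %in% c("full_dGGCCTGn", "full_dGGCCTGr")
  lens <- nchar(sp$tract[full])
  reps <- counts[full]
  stat <- function(x, f) if (length(x)) as.integer(f(x)) else NA_integer_
  data.frame(sample_id = sampleId,
             subread_number = nrow(sp),
             n_650plus = sum(isPathogenic(counts, threshold)),
             ratio_650plus = pathogenicRatio(
               sum(isPathogenic(counts, threshold)), nrow(sp)),
             full_count = sum(full),
             max_length_bp = stat(lens, max),
             mean_length_bp = stat(lens, function(x) roundHalfUp(mean(x))),
             min_length_bp = stat(lens, min),
             max_repeats = stat(reps, max),
             mean_repeats = stat(reps, function(x) roundHalfUp(mean(x))),
             min_repeats = stat(reps, min),
             full_fwd = sum(sp$span_class == "full_dGGCCTGn"),
             full_rev = sum(sp$span_class == "full_dGGCCTGr"),
             stringsAsFactors = FALSE)
}

#' Combine per-sample summaries
#'
#' @param summaries List of rows from [summarizeSample()].
#' @return `data.frame` with one row per sample.
#' @export
summarizeSamples <- function(summaries) {
  do.call(rbind, summaries)
}

#' Write the per-sample summary in report column order
#'
#' TSV columns follow the published per-sample table layout (sample,
#' subread number, pathogenic count and ratio, full-length count, then
#' max/mean/min length and repeat number), with the forward/reverse full
#' split appended as detail columns; a JSON mirror is written alongside
#' when `json = TRUE`.
#'
#' @param summary `data.frame` from [summarizeSamples()].
#' @param path Output TSV path.
#' @param json Also write `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeSummaryTsv <- function(summary, path, json = TRUE) {
  out <- summary[, c("sample_id", "subread_number", "n_650plus",
                     "ratio_650plus", "full_count", "max_length_bp",
                     "mean_length_bp", "min_length_bp", "max_repeats",
                     "mean_repeats", "min_repeats", "full_fwd",
                     "full_rev")]
  names(out) <- c("Sample ID", "Subread number", "dGGCCTG 650+",
                  "dGGCCTG 650+ ratio", "Full dGGCCTGn", "Max length (bp)",
                  "Mean length (bp)", "Min length (bp)",
                  "Max number of repeats", "Mean number of repeats",
                  "Min number of repeats", "Full forward", "Full reverse")
  out[["dGGCCTG 650+ ratio"]] <- sprintf("%.2f",
                                         summary$ratio_650plus)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (json)
    jsonlite::write_json(summary, paste0(path, ".json"),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
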