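#' Waterfall schematic of a tokenized tract
#'
#' Draws one rectangle per motif token, row-wrapped `rowWidth` tokens per
#' row and read 5' (upper left) to 3' (lower right). Rectangle widths are
#' proportional to token length; colours come from the catalog (de-novo
#' labels get deterministic palette colours), and labels in `rareLabels`
#' -- conventionally motifs below 1% of pooled full-length nucleotides --
#' are blacked out. The SVG text is a pure function of its inputs, so
#' identical inputs give byte-identical files.
#'
#' @param tokenized A [TokenizedTract-class].
#' @param catalog A [MotifCatalog-class] (colour key).
#' @param rareLabels Labels rendered black (see [rareMotifLabels()]).
#' @param rowWidth Tokens per row (default 50).
#' @param pxPerBp,rowHeight,rowGap Geometry in pixels.
#' @param title Optional title text.
#' @param file Optional output path; the SVG text is also returned.
#' @return The SVG document as a single character string, invisibly when
#'   `file` is given.
#' @export
renderWaterfall <- function(tokenized, catalog = MotifCatalog(),
                            rareLabels = character(0), rowWidth = 50,
                            pxPerBp = 2, rowHeight = 12, rowGap = 2,
                            title = NULL, file = NULL) {
  tk <- tokenTable(tokenized)
  pad <- 10
  titleH <- if (is.null(title)) 0 else 18
  if (!nrow(tk)) {
    warning("empty tokenization; rendering empty canvas")
    svg <- paste0('<svg xmlns="http://www.w3.org/2000/svg" width="100" ',
                  'height="20"></svg>\n')
    if (!is.null(file)) { writeLines(svg, file, sep = ""); return(invisible(svg)) }
    return(svg)
  }
  w <- (tk$end - tk$start) * pxPerBp
  row <- (seq_len(nrow(tk)) - 1L) %/% rowWidth
  x <- unlist(lapply(split(w, row), function(v) cumsum(c(0, v[-length(v)]))))
  y <- row * (rowHeight + rowGap)
  col <- motifColor(tk$label, catalog)
  col[tk$label %in% rareLabels] <- "#000000"
  rects <- sprintf(
    '<rect x="%.1f" y="%.1f" width="%.1f" height="%d" fill="%s"><title>%s</title></rect>',
    pad + x, pad + titleH + y, w, rowHeight, col, tk$label)
  width <- pad * 2 + max(tapply(x + w, row, max))
  height <- pad * 2 + titleH + max(y) + rowHeight
  head <- sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                         'width="%.0f" height="%.0f">'), width, height)
  titleEl <- if (is.null(title)) character(0) else
    sprintf('<text x="%d" y="%d" font-size="12" font-family="sans-serif">%s</text>',
            pad, pad + 12, title)
  svg <- paste(c(head, titleEl, rects, "</svg>", ""), collapse = "\n")
  if (!is.null(file)) {
    writeLines(svg, file, sep = "")
    return(invisible(svg))
  }
  svg
}

#' Distribution plots of classified subreads
#'
#' Builds the standard diagnostic panels: spanning-class counts per
#' sample, and the length and core-repeat-number distributions of
#' full-length tracts per sample.
#'
#' @param classified `data.frame` from [classifyReads()] over all samples
#'   (must carry `sample_id`).
#' @param fullStats `data.frame` with sample_id, tract_length and
#'   core_count for full-length tracts (e.g. from [fullLengthStats()]).
#' @return Named list of ggplot objects: `class_counts`, `length`,
#'   `repeats`.
#' @export
plotDistributions <- function(classified, fullStats) {
  cls <- factor(classified$span_class, levels = spanClasses())
  dfc <- data.frame(sample_id = classified$sample_id, span_class = cls)
  p1 <- ggplot2::ggplot(dfc,
          ggplot2::aes(x = span_class, fill = sample_id)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(x = "span class", y = "subreads",
                  title = "Spanning-read classification") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
  p2 <- ggplot2::ggplot(fullStats,
          ggplot2::aes(x = tract_length, colour = sample_id)) +
    ggplot2::geom_freqpoly(bins = 30) +
    ggplot2::labs(x = "full-length tract length (bp)", y = "subreads",
                  title = "Full-length tract length distribution") +
    ggplot2::theme_bw()
  p3 <- ggplot2::ggplot(fullStats,
          ggplot2::aes(x = core_count, colour = sample_id)) +
    ggplot2::geom_freqpoly(bins = 30) +
    ggplot2::labs(x = "core repeat number", y = "subreads",
                  title = "Full-length repeat number distribution") +
    ggplot2::theme_bw()
  list(class_counts = p1, length = p2, repeats = p3)
}

#' Per-read statistics of full-length tracts
#'
#' @param classified `data.frame` from [classifyReads()].
#' @param catalog A [MotifCatalog-class].
#' @param countMode Passed to [countCoreRepeats()].
#' @return `data.frame` with sample_id, read_id, tract_length, core_count
#'   for full-spanning reads.
#' @export
fullLengthStats <- function(classified, catalog = MotifCatalog(),
                            countMode = "dp") {
  full <- classified[classified$span_class %in%
                       c("full_dGGCCTGn", "full_dGGCCTGr"), , drop = FALSE]
  data.frame(sample_id = full$sample_id, read_id = full$read_id,
             tract_length = nchar(full$tract),
             core_count = vapply(full$tract, countCoreRepeats, integer(1),
                                 catalog = catalog, mode = countMode,
                                 USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Write a minimal HTML index for a run directory
#'
#' Links every table and figure found under the run directory.
#'
#' @param dir Run directory.
#' @return Path of the written `index.html`, invisibly.
#' @export
writeRunReport <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE))
  files <- files[!files %in% "index.html"]
  items <- sprintf('<li><a href="%s">%s</a></li>', files, files)
  html <- c("<!DOCTYPE html>", "<html><head><title>RepeatSpan run</title>",
            "</head><body>", "<h1>RepeatSpan run report</h1>", "<ul>",
            items, "</ul>", "</body></html>")
  out <- file.path(dir, "index.html")
  writeLines(html, out)
  invisible(out)
}

utils::globalVariables(c("span_class", "sample_id", "tract_length",
                         "core_count"))
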