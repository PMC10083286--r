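#' MotifCatalog: the core repeat unit and its interruption variants
#'
#' Holds the canonical repeat unit of a tandem-repeat locus together with
#' the variant (interruption) units observed interspersed in expanded
#' alleles, and a display colour per motif. The defaults describe the
#' SCA36-associated GGCCTG hexanucleotide repeat in intron 1 of NOP56,
#' whose expansions carry GGCTG, GGCCCTG, GGCCG and GGCCTTG interruptions.
#'
#' @slot core Core repeat unit (uppercase A/C/G/T).
#' @slot variants Distinct variant units, none equal to the core.
#' @slot colors Named vector of display colours covering core and variants.
#'
#' @seealso [tokenize()], [generateAllele()]
#' @name MotifCatalog-class
#' @exportClass MotifCatalog
setClass("MotifCatalog",
  representation(core = "character", variants = "character",
                 colors = "character"))

setValidity("MotifCatalog", function(object) {
  msg <- character(0)
  if (length(object@core) != 1L || !nzchar(object@core) ||
      grepl("[^ACGT]", object@core))
    msg <- c(msg, "'core' must be a non-empty uppercase ACGT string")
  if (anyDuplicated(object@variants))
    msg <- c(msg, "'variants' must be distinct")
  if (object@core %in% object@variants)
    msg <- c(msg, "no variant may equal the core motif")
  if (length(object@variants) &&
      any(!nzchar(object@variants) | grepl("[^ACGT]", object@variants)))
    msg <- c(msg, "variants must be uppercase ACGT strings")
  lens <- nchar(c(object@core, object@variants))
  if (any(lens < 4L | lens > 8L))
    msg <- c(msg, "all motif lengths must lie in [4, 8]")
  motifs <- c(object@core, object@variants)
  if (!all(motifs %in% names(object@colors)))
    msg <- c(msg, "'colors' must name every motif")
  if (length(msg)) msg else TRUE
})

## fixed palette cycled deterministically for motifs without an assigned colour
.motifPalette <- c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
                   "#8C564B", "#E377C2", "#BCBD22", "#17BECF", "#AEC7E8")

#' Construct a motif catalog
#'
#' @param core Core repeat unit; default the SCA36 GGCCTG hexanucleotide.
#' @param variants Interruption units; default the four variants seen in
#'   NOP56 expansion tracts.
#' @param colors Optional named colour vector; missing motifs are assigned
#'   deterministic colours from a fixed palette.
#' @return A [MotifCatalog-class] object.
#' @examples
#' cat6 <- MotifCatalog()
#' coreMotif(cat6)
#' variantMotifs(cat6)
#' @export
MotifCatalog <- function(core = "GGCCTG",
                         variants = c("GGCTG", "GGCCCTG", "GGCCG",
                                      "GGCCTTG"),
                         colors = NULL) {
  motifs <- c(core, variants)
  full <- setNames(.motifPalette[(seq_along(motifs) - 1L) %%
                                   length(.motifPalette) + 1L], motifs)
  if (!is.null(colors)) full[names(colors)] <- colors
  new("MotifCatalog", core = core, variants = as.character(variants),
      colors = full)
}

#' @describeIn MotifCatalog-class Core repeat unit.
#' @param x A `MotifCatalog`.
#' @export
setGeneric("coreMotif", function(x) standardGeneric("coreMotif"))

#' @rdname MotifCatalog-class
#' @export
setMethod("coreMotif", "MotifCatalog", function(x) x@core)

#' @describeIn MotifCatalog-class Variant (interruption) units.
#' @export
setGeneric("variantMotifs", function(x) standardGeneric("variantMotifs"))

#' @rdname MotifCatalog-class
#' @export
setMethod("variantMotifs", "MotifCatalog", function(x) x@variants)

#' @describeIn MotifCatalog-class Core plus variants, core first.
#' @export
setGeneric("catalogMotifs", function(x) standardGeneric("catalogMotifs"))

#' @rdname MotifCatalog-class
#' @export
setMethod("catalogMotifs", "MotifCatalog",
          function(x) c(x@core, x@variants))

#' @describeIn MotifCatalog-class Named display colours.
#' @export
setGeneric("motifColors", function(x) standardGeneric("motifColors"))

#' @rdname MotifCatalog-class
#' @export
setMethod("motifColors", "MotifCatalog", function(x) x@colors)

setMethod("show", "MotifCatalog", function(object) {
  cat("MotifCatalog\n")
  cat("  core:    ", object@core, "\n", sep = "")
  cat("  variants:", paste(object@variants, collapse = ", "), "\n")
})

## Deterministic colour for any motif label (catalog colour when assigned,
## otherwise a palette entry keyed by a simple label hash); "other" is grey.
motifColor <- function(label, catalog) {
  cols <- motifColors(catalog)
  vapply(label, function(l) {
    if (l == "other") return("#BBBBBB")
    if (l %in% names(cols)) return(unname(cols[[l]]))
    h <- sum(utf8ToInt(l) * seq_len(nchar(l)))
    .motifPalette[h %% length(.motifPalette) + 1L]
  }, character(1), USE.NAMES = FALSE)
}
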