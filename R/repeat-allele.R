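#' RepeatAllele: one haplotype's ordered repeat tract
#'
#' An ordered list of motif tokens defining the repeat tract of a single
#' allele. The concatenation of the tokens is the tract sequence; the
#' number of tokens equal to the core motif is the allele's core repeat
#' count (the quantity compared against the pathogenic threshold).
#'
#' @slot tokens Ordered motif strings (core and interruption units).
#' @slot core The core motif the allele is defined against.
#'
#' @seealso [generateAllele()], [generateLocus()]
#' @name RepeatAllele-class
#' @exportClass RepeatAllele
setClass("RepeatAllele",
  representation(tokens = "character", core = "character"))

setValidity("RepeatAllele", function(object) {
  msg <- character(0)
  if (length(object@tokens) < 1L)
    msg <- c(msg, "an allele needs at least one token")
  if (any(!nzchar(object@tokens) | grepl("[^ACGT]", object@tokens)))
    msg <- c(msg, "tokens must be uppercase ACGT strings")
  if (length(object@core) != 1L || !nzchar(object@core))
    msg <- c(msg, "'core' must be a single motif")
  if (length(msg)) msg else TRUE
})

#' Construct a repeat allele from motif tokens
#'
#' @param tokens Character vector of motif units, 5' to 3'.
#' @param core Core motif (default `"GGCCTG"`).
#' @return A [RepeatAllele-class] object.
#' @examples
#' a <- RepeatAllele(rep("GGCCTG", 4))
#' coreCount(a)
#' tractLength(a)
#' @export
RepeatAllele <- function(tokens, core = "GGCCTG") {
  new("RepeatAllele", tokens = as.character(tokens), core = core)
}

#' @describeIn RepeatAllele-class The ordered motif tokens.
#' @param x A `RepeatAllele`.
#' @export
setGeneric("alleleTokens", function(x) standardGeneric("alleleTokens"))

#' @rdname RepeatAllele-class
#' @export
setMethod("alleleTokens", "RepeatAllele", function(x) x@tokens)

#' @describeIn RepeatAllele-class Concatenated tract sequence.
#' @export
setGeneric("tract", function(x) standardGeneric("tract"))

#' @rdname RepeatAllele-class
#' @export
setMethod("tract", "RepeatAllele",
          function(x) paste(x@tokens, collapse = ""))

#' @describeIn RepeatAllele-class Number of tokens equal to the core motif.
#' @export
setGeneric("coreCount", function(x) standardGeneric("coreCount"))

#' @rdname RepeatAllele-class
#' @export
setMethod("coreCount", "RepeatAllele",
          function(x) sum(x@tokens == x@core))

#' @describeIn RepeatAllele-class Tract length in bp.
#' @export
setGeneric("tractLength", function(x) standardGeneric("tractLength"))

#' @rdname RepeatAllele-class
#' @export
setMethod("tractLength", "RepeatAllele",
          function(x) sum(nchar(x@tokens)))

setMethod("show", "RepeatAllele", function(object) {
  cat("RepeatAllele:", length(object@tokens), "tokens,",
      coreCount(object), "x core", paste0("(", object@core, "),"),
      tractLength(object), "bp\n")
})
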