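#' Round half away from zero
#'
#' Decimal rounding in which exact halves round up (away from zero), the
#' convention used for the reported pathogenic-repeat ratios, rather than
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' roundHalfUp(100 * 9 / 76, 2)   # 11.84
#' roundHalfUp(0.125, 2)          # 0.13
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon guards against values like 14.195 stored just below the half
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Reverse-complement a DNA string
#'
#' @param x Single character string over A/C/G/T.
#' @return The reverse complement, as a character string.
#' @examples
#' revComp("GGCCTG")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Run expr with a fixed RNG state, restoring the caller's stream afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer")
    old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

assertDna <- function(x, what = "sequence", allowEmpty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single character string", what))
  if (!allowEmpty && !nzchar(x))
    stop(sprintf("'%s' must be non-empty", what))
  if (nzchar(x) && grepl("[^ACGT]", x))
    stop(sprintf("'%s' contains characters outside A/C/G/T", what))
  invisible(x)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Span class labels, in reporting order.
spanClasses <- function() {
  c("full_dGGCCTGn", "5p_GGCCTGn", "3p_GGCCTGn", "full_dGGCCTGr",
    "non_spanning")
}

#' Write reads as FASTQ
#'
#' Plain 4-line FASTQ records with a constant quality character; downstream
#' stages never consume base qualities.
#'
#' @param reads Named character vector or [Biostrings::DNAStringSet].
#' @param path Output file.
#' @param qualChar Single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path, qualChar = "?") {
  seqs <- as.character(reads)
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(seqs))
  rec <- vapply(seq_along(seqs), function(i) {
    paste0("@", ids[i], "\n", seqs[i], "\n+\n",
           strrep(qualChar, nchar(seqs[i])))
  }, character(1))
  writeLines(rec, path)
  invisible(path)
}

#' Read long reads from FASTA or FASTQ
#'
#' @param path Input file; format inferred from the first character.
#' @return A [Biostrings::DNAStringSet] named by read id.
#' @export
readReads <- function(path) {
  first <- readChar(path, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

writeFastaOne <- function(seq, path, header) {
  writeLines(c(paste0(">", header),
               gsub("(.{80})", "\\1\n", seq, perl = TRUE)), path)
  invisible(path)
}
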