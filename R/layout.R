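#' Describe the geometry of a sequenced ditag
#'
#' A 5'-SAGE ditag packages two short 5' tags into one ~100 bp sequencing
#' unit: a 5' adapter, the first tag in transcript orientation, a fixed
#' linker, the second tag stored reverse-complemented (tail-to-tail
#' ligation), and a 3' adapter. The adapter and linker sequences are a
#' modelling choice (the library chemistry does not prescribe readable
#' sequences) and are fully configurable.
#'
#' @param adapter_5,linker,adapter_3 DNA strings flanking and separating
#'   the two tags.
#' @param tag_length_range integer length-2 vector, inclusive range of tag
#'   lengths in bases. MmeI-style tagging yields 15-20 bp tags.
#' @param ditag_total_length nominal total ditag length in bases; the
#'   constructor checks that the fixed parts plus two tags can reach it.
#' @return an object of class `ditag_layout`.
#' @examples
#' layout <- ditag_layout()
#' layout$tag_length_range
#' @export
ditag_layout <- function(adapter_5 = "TTCCGGTACGACTGAGCTACC",
                         linker = "GTGCTCGAATTCAAGCTTCTAACGATG",
                         adapter_3 = "CCATCGAGTCAGCATGGTACC",
                         tag_length_range = c(15L, 20L),
                         ditag_total_length = 100L) {
  if (!all(is_dna(c(adapter_5, linker, adapter_3), allow_n = FALSE))) {
    stopf("adapters and linker must be plain A/C/G/T sequences")
  }
  tag_length_range <- as.integer(tag_length_range)
  if (length(tag_length_range) != 2L || any(tag_length_range < 1L) ||
      tag_length_range[1] > tag_length_range[2]) {
    stopf("tag_length_range must be an increasing pair of positive lengths")
  }
  fixed <- nchar(adapter_5) + nchar(linker) + nchar(adapter_3)
  lo <- fixed + 2L * tag_length_range[1]
  hi <- fixed + 2L * tag_length_range[2]
  if (ditag_total_length < lo || ditag_total_length > hi) {
    stopf("ditag_total_length %d unreachable: fixed parts + two tags span [%d, %d]",
          ditag_total_length, lo, hi)
  }
  structure(
    list(adapter_5 = adapter_5, linker = linker, adapter_3 = adapter_3,
         tag_length_range = tag_length_range,
         ditag_total_length = as.integer(ditag_total_length)),
    class = "ditag_layout"
  )
}

#' @export
print.ditag_layout <- function(x, ...) {
  cat("ditag layout:\n")
  cat("  5' adapter :", x$adapter_5, "\n")
  cat("  linker     :", x$linker, "\n")
  cat("  3' adapter :", x$adapter_3, "\n")
  cat(sprintf("  tag length : %d-%d bp, nominal ditag %d bp\n",
              x$tag_length_range[1], x$tag_length_range[2],
              x$ditag_total_length))
  invisible(x)
}
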