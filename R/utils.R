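# Internal helpers shared across modules.

# data.table is used via :: only; opt in to its [ semantics.
.datatable.aware <- TRUE

#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA of length n at the requested GC content.
random_dna <- function(n, gc_content) {
  probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
             (1 - gc_content) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

# Decode a Sanger Phred+33 quality string into integer scores.
decode_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

encode_phred <- function(scores) {
  intToUtf8(scores + 33L)
}

is_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Chromosome widths as a named integer vector, from a DNAStringSet or a
# named character vector of sequences.
chrom_lengths <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(Biostrings::width(genome), names(genome))
  } else {
    stats::setNames(nchar(genome), names(genome))
  }
}

genome_as_character <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else {
    genome
  }
}
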