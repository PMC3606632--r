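#' Simulate two-stage ditag read sets with per-tag ground truth
#'
#' Draws 5' tags from each stage's expected gene shares, packages them two
#' per read as adapter-flanked ditags (second tag reverse-complemented
#' after the linker), applies per-base substitution errors to the tag
#' sequences, and emits a truth table recording every tag's gene of
#' origin, 5'-end genomic coordinate and strand.
#'
#' Sense tags start at a TSS drawn from the gene's TSS profile (an offset
#' of 1-500 bases upstream of the start codon, on the coding strand).
#' Antisense tags are drawn uniformly from within the gene body on the
#' opposite strand. A tag whose window would extend past a chromosome end
#' is resampled. Read qualities are constant Q40 except for a configurable
#' fraction of degraded reads (constant `degraded_q`), included to exercise
#' the quality filter.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character vector.
#' @param models gene-model data.frame from [generate_genome()].
#' @param truths truth table from [simulate_truth()].
#' @param layout a [ditag_layout()].
#' @param n_reads_per_stage integer pair: ditag reads per stage; each read
#'   carries two tags.
#' @param error_rate per-base substitution probability in `[0, 0.1]`.
#' @param seed integer seed.
#' @param stages labels for the two libraries.
#' @param degraded_read_fraction fraction of reads whose qualities are
#'   uniformly degraded to `degraded_q`.
#' @param degraded_q Phred score of degraded reads.
#' @return list with `reads` (named list of per-stage data.frames:
#'   read_id, sequence, qualities) and `truth` (data.frame: stage, read_id,
#'   slot, gene_id, tss, strand, antisense, tag, degraded). The truth table
#'   has exactly two rows per read.
#' @export
simulate_reads <- function(genome, models, truths, layout,
                           n_reads_per_stage = c(2000L, 3000L),
                           error_rate = 0, seed = 1L,
                           stages = c("Myc", "S1-Pri"),
                           degraded_read_fraction = 0.02,
                           degraded_q = 8L) {
  stopifnot(inherits(layout, "ditag_layout"))
  if (any(n_reads_per_stage < 1L)) stopf("n_reads_per_stage must be positive")
  if (error_rate < 0 || error_rate > 0.1) {
    stopf("error_rate must lie in [0, 0.1]")
  }
  seqs <- genome_as_character(genome)
  lens <- chrom_lengths(genome)
  for (pat in c(layout$adapter_5, layout$linker, layout$adapter_3)) {
    hits <- sum(Biostrings::vcountPattern(pat, Biostrings::DNAStringSet(seqs))) +
      sum(Biostrings::vcountPattern(revcomp(pat), Biostrings::DNAStringSet(seqs)))
    if (hits > 0L) {
      warning(sprintf(
        "layout sequence %s occurs in the genome (%d site[s]); ditag extraction may be ambiguous",
        pat, hits), call. = FALSE)
    }
  }
  midx <- match(truths$gene_id, models$gene_id)
  if (anyNA(midx)) stopf("truth table contains genes absent from the models")

  withr::with_seed(seed, {
    out_reads <- list()
    out_truth <- list()
    for (s in seq_along(stages)) {
      stage <- stages[s]
      n_reads <- as.integer(n_reads_per_stage[s])
      n_tags <- 2L * n_reads
      share <- if (s == 1L) truths$abundance_myc else truths$abundance_pri
      gidx <- sample.int(nrow(truths), n_tags, replace = TRUE, prob = share)
      tags <- draw_tags(gidx, truths, models[midx, , drop = FALSE],
                        seqs, lens, layout)
      if (error_rate > 0) {
        tags$tag <- mutate_tags(tags$tag, error_rate)
      }
      read_id <- sprintf("%s_read_%06d", gsub("[^A-Za-z0-9]", "", stage),
                         seq_len(n_reads))
      i1 <- seq_len(n_reads) * 2L - 1L
      i2 <- i1 + 1L
      read_seq <- paste0(layout$adapter_5, tags$tag[i1], layout$linker,
                         revcomp(tags$tag[i2]), layout$adapter_3)
      degraded <- stats::runif(n_reads) < degraded_read_fraction
      quals <- vapply(seq_len(n_reads), function(i) {
        q <- if (degraded[i]) degraded_q else 40L
        encode_phred(rep(q, nchar(read_seq[i])))
      }, character(1))
      out_reads[[stage]] <- data.frame(read_id = read_id,
                                       sequence = read_seq,
                                       qualities = quals,
                                       stringsAsFactors = FALSE)
      out_truth[[stage]] <- data.frame(
        stage = stage,
        read_id = rep(read_id, each = 2L),
        slot = rep(1:2, n_reads),
        gene_id = truths$gene_id[gidx],
        tss = tags$tss, strand = tags$strand,
        antisense = tags$antisense, tag = tags$tag,
        degraded = rep(degraded, each = 2L),
        stringsAsFactors = FALSE)
    }
    list(reads = out_reads, truth = do.call(rbind, out_truth))
  })
}

# Draw one tag per entry of gidx; models must be row-aligned with truths.
draw_tags <- function(gidx, truths, models, seqs, lens, layout) {
  n <- length(gidx)
  lo <- layout$tag_length_range[1]
  hi <- layout$tag_length_range[2]
  tag <- character(n); tss <- integer(n); strand <- character(n)
  anti <- stats::runif(n) < truths$antisense_fraction[gidx]
  for (i in seq_len(n)) {
    g <- gidx[i]
    chrom <- models$chrom[g]
    L <- lens[[chrom]]
    for (attempt in 1:50) {
      len <- sample(lo:hi, 1L)
      if (anti[i]) {
        pos <- positioned_antisense(models$gene_left[g], models$gene_right[g],
                                    models$strand[g], len)
        if (is.null(pos)) next
      } else {
        prof <- truths$tss_profile[[g]]
        off <- prof$offset[sample.int(nrow(prof), 1L, prob = prof$weight)]
        if (models$strand[g] == "+") {
          pos <- list(coord = models$coding_start[g] - off, strand = "+")
        } else {
          pos <- list(coord = models$coding_start[g] + off, strand = "-")
        }
      }
      span <- if (pos$strand == "+") c(pos$coord, pos$coord + len - 1L)
              else c(pos$coord - len + 1L, pos$coord)
      if (span[1] < 1L || span[2] > L) next  # resample at chromosome edge
      raw <- substr(seqs[[chrom]], span[1], span[2])
      tag[i] <- if (pos$strand == "+") raw else revcomp(raw)
      tss[i] <- pos$coord
      strand[i] <- pos$strand
      break
    }
    if (tag[i] == "") stopf("failed to place a tag for gene %s", models$gene_id[g])
  }
  list(tag = tag, tss = tss, strand = strand, antisense = anti)
}

# Uniform 5'-end position on the strand opposite the gene, with the whole
# tag inside the gene body; NULL when the body is shorter than the tag.
positioned_antisense <- function(left, right, gene_strand, len) {
  if (right - left + 1L < len) return(NULL)
  if (gene_strand == "+") {
    # antisense tag on "-": 5' end is its higher coordinate
    coord <- sample(seq(left + len - 1L, right), 1L)
    list(coord = coord, strand = "-")
  } else {
    coord <- sample(seq(left, right - len + 1L), 1L)
    list(coord = coord, strand = "+")
  }
}

# Per-base substitutions at a fixed rate; substituted bases always change.
mutate_tags <- function(tags, error_rate) {
  vapply(tags, function(tg) {
    b <- strsplit(tg, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(b)) < error_rate)
    for (j in hit) {
      b[j] <- sample(setdiff(c("A", "C", "G", "T"), b[j]), 1L)
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write reads to FASTQ (Sanger Phred+33)
#' @param reads per-stage read data.frame from [simulate_reads()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities))
  invisible(path)
}

#' Read a FASTQ file into the package's read layout
#' @param path FASTQ file (Sanger Phred+33).
#' @return data.frame with columns read_id, sequence, qualities.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  df <- data.frame(read_id = names(x), sequence = as.character(x),
                   qualities = as.character(q), stringsAsFactors = FALSE)
  bad <- nchar(df$sequence) != nchar(df$qualities)
  if (any(bad)) {
    stopf("malformed FASTQ record(s): %s",
          paste(df$read_id[bad], collapse = ", "))
  }
  rownames(df) <- NULL
  df
}
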