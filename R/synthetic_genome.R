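#' Specification for a toy genome with packed gene models
#'
#' Parameters for the synthetic genome generator. Defaults emulate a
#' gene-dense basidiomycete chromosome at desk scale: ~1-2 kb genes with
#' ~1.1 kb minimum intergenic spacing (so that the 500 bp promoter/UTR
#' windows of neighbouring genes never reach into another gene's body,
#' mirroring the compact layout of the 37.5 Mb reference at reduced size).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of every chromosome in bases.
#' @param n_genes total number of genes, distributed evenly over
#'   chromosomes.
#' @param gene_length_range inclusive range of gene (coding span) lengths.
#' @param intergenic_min minimum gap in bases between adjacent gene spans.
#' @param gc_content fraction of G+C in the random background sequence.
#' @param duplicated_region_fraction fraction of each chromosome that is an
#'   exact internal duplication, used to create multi-mapping tags.
#' @param seed integer seed; the same seed reproduces byte-identical
#'   genome and gene models.
#' @return an object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 3L,
                        chromosome_length = 35000L,
                        n_genes = 30L,
                        gene_length_range = c(900L, 2100L),
                        intergenic_min = 1100L,
                        gc_content = 0.5,
                        duplicated_region_fraction = 0,
                        seed = 1L) {
  spec <- list(n_chromosomes = as.integer(n_chromosomes),
               chromosome_length = as.integer(chromosome_length),
               n_genes = as.integer(n_genes),
               gene_length_range = as.integer(gene_length_range),
               intergenic_min = as.integer(intergenic_min),
               gc_content = gc_content,
               duplicated_region_fraction = duplicated_region_fraction,
               seed = as.integer(seed))
  if (spec$n_chromosomes < 1L) stopf("need at least one chromosome")
  if (spec$gc_content < 0 || spec$gc_content > 1) {
    stopf("gc_content must lie in [0, 1]")
  }
  if (spec$duplicated_region_fraction < 0 || spec$duplicated_region_fraction > 1) {
    stopf("duplicated_region_fraction must lie in [0, 1]")
  }
  if (spec$n_genes < 0L) stopf("n_genes must be non-negative")
  if (length(spec$gene_length_range) != 2L ||
      spec$gene_length_range[1] > spec$gene_length_range[2] ||
      spec$gene_length_range[1] < 1L) {
    stopf("gene_length_range must be an increasing pair of positive lengths")
  }
  structure(spec, class = "genome_spec")
}

# Margin kept gene-free at each chromosome end so that every [start-500,
# stop+500] window lies inside its chromosome.
UTR_WINDOW <- 500L

#' Generate a toy genome and gene models
#'
#' Random chromosomes at the requested GC content, with gene spans packed
#' left to right under the minimum-spacing constraint and strands drawn at
#' random. Translation coordinates follow transcript orientation:
#' `coding_start` is the first base of the start codon (the higher genomic
#' coordinate for minus-strand genes) and `coding_end` the last base of the
#' stop codon. When `duplicated_region_fraction > 0`, a segment of each
#' chromosome is copied over an intergenic region well away from any gene
#' window, creating exact internal repeats and hence multi-mapping tags.
#'
#' @param spec a [genome_spec()].
#' @return a list with elements `genome` (named [Biostrings::DNAStringSet]),
#'   `models` (data.frame: gene_id, chrom, strand, gene_left, gene_right,
#'   coding_start, coding_end) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  chroms <- sprintf("chr%d", seq_len(spec$n_chromosomes))
  seqs <- vapply(chroms, function(ch) {
    random_dna(spec$chromosome_length, spec$gc_content)
  }, character(1))

  # Spread genes over chromosomes as evenly as possible.
  per_chrom <- rep(spec$n_genes %/% spec$n_chromosomes, spec$n_chromosomes)
  extra <- spec$n_genes %% spec$n_chromosomes
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  models <- list()
  gid <- 0L
  for (i in seq_along(chroms)) {
    k <- per_chrom[i]
    if (k == 0L) next
    lens <- sample(seq(spec$gene_length_range[1], spec$gene_length_range[2]),
                   k, replace = TRUE)
    need <- 2L * (UTR_WINDOW + 1L) + sum(lens) +
      (k - 1L) * spec$intergenic_min
    if (need > spec$chromosome_length) {
      stopf(paste0("cannot pack %d genes of %d-%d bp with %d bp spacing into ",
                   "a %d bp chromosome (needs >= %d bp)"),
            k, spec$gene_length_range[1], spec$gene_length_range[2],
            spec$intergenic_min, spec$chromosome_length, need)
    }
    slack <- spec$chromosome_length - need
    # Split the slack over the k+1 gaps with a uniform stick-breaking draw.
    cuts <- sort(stats::runif(k))
    gaps <- floor(diff(c(0, cuts, 1)) * slack)
    left <- UTR_WINDOW + 1L + gaps[1]
    for (j in seq_len(k)) {
      gid <- gid + 1L
      right <- left + lens[j] - 1L
      strand <- sample(c("+", "-"), 1L)
      models[[gid]] <- data.frame(
        gene_id = sprintf("GENE_%04d", gid),
        chrom = chroms[i], strand = strand,
        gene_left = left, gene_right = right,
        coding_start = if (strand == "+") left else right,
        coding_end = if (strand == "+") right else left,
        stringsAsFactors = FALSE)
      left <- right + 1L + spec$intergenic_min +
        if (j < k) gaps[j + 1L] else 0L
    }
  }
  models <- if (length(models)) do.call(rbind, models) else empty_models()

  if (spec$duplicated_region_fraction > 0) {
    seqs <- duplicate_regions(seqs, models, spec)
  }

  list(genome = Biostrings::DNAStringSet(seqs), models = models, spec = spec)
}

empty_models <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             strand = character(0), gene_left = integer(0),
             gene_right = integer(0), coding_start = integer(0),
             coding_end = integer(0), stringsAsFactors = FALSE)
}

# Copy a segment of each chromosome over gene-free ground, so a configured
# fraction of the sequence is an exact internal duplication. Destination
# intervals stay clear of every gene's [left-500, right+500] window (plus a
# buffer of one maximal tag length so no emitted tag can straddle into a
# duplicated region).
duplicate_regions <- function(seqs, models, spec, buffer = 25L) {
  for (i in seq_along(seqs)) {
    ch <- names(seqs)[i]
    L <- nchar(seqs[i])
    target <- floor(spec$duplicated_region_fraction * L)
    if (target < 20L) next
    m <- models[models$chrom == ch, , drop = FALSE]
    blocked <- IRanges::IRanges(start = integer(0), end = integer(0))
    if (nrow(m)) {
      blocked <- IRanges::IRanges(
        start = pmax(1L, m$gene_left - UTR_WINDOW - buffer),
        end = pmin(L, m$gene_right + UTR_WINDOW + buffer))
    }
    free <- IRanges::setdiff(IRanges::IRanges(1L, L), blocked)
    free <- free[IRanges::width(free) >= 40L]
    if (length(free) == 0L) next
    # Fill the widest free interval: left half is the source, right half
    # receives the copy.
    widest <- free[which.max(IRanges::width(free))]
    seg <- min(target, IRanges::width(widest) %/% 2L)
    if (seg < 20L) next
    src_start <- IRanges::start(widest)
    dst_start <- src_start + seg
    segment <- substr(seqs[i], src_start, src_start + seg - 1L)
    substr(seqs[i], dst_start, dst_start + seg - 1L) <- segment
  }
  seqs
}

#' Write a genome to FASTA
#' @param genome named [Biostrings::DNAStringSet] (or named character).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' One `gene` feature per model, 1-based inclusive coordinates, with the
#' transcript-orientation translation coordinates carried in the
#' `coding_start`/`coding_end` attributes.
#'
#' @param models gene-model data.frame as returned by [generate_genome()].
#' @param genome the matching genome (for sequence lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_models_gff3 <- function(models, genome, path) {
  lens <- chrom_lengths(genome)
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(models$gene_left, models$gene_right),
    strand = models$strand,
    type = rep("gene", nrow(models)),
    ID = models$gene_id,
    coding_start = models$coding_start,
    coding_end = models$coding_end,
    seqlengths = lens)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path a GFF3 file written by [write_models_gff3()] (or any GFF3
#'   whose `gene` features carry an `ID`).
#' @return gene-model data.frame in the layout of [generate_genome()].
#' @export
read_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  strand <- as.character(GenomicRanges::strand(gr))
  left <- GenomicRanges::start(gr)
  right <- GenomicRanges::end(gr)
  cs <- if (!is.null(gr$coding_start)) as.integer(gr$coding_start) else
    ifelse(strand == "+", left, right)
  ce <- if (!is.null(gr$coding_end)) as.integer(gr$coding_end) else
    ifelse(strand == "+", right, left)
  data.frame(gene_id = as.character(gr$ID),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             strand = strand, gene_left = left, gene_right = right,
             coding_start = cs, coding_end = ce, stringsAsFactors = FALSE)
}
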