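#' Build an exact-match genome index for a set of tag lengths
#'
#' Hash-style lookup from k-mer to genomic location, covering both strands
#' for every requested length. Locations follow the tag coordinate
#' convention used throughout the package: the 1-based position of the
#' tag's 5' end in transcript orientation, i.e. the leftmost base for
#' plus-strand hits and the rightmost base for minus-strand hits. This
#' makes the reported position of a 5' tag its candidate TSS.
#'
#' @param genome named [Biostrings::DNAStringSet] or named character.
#' @param lengths integer vector of tag lengths to index.
#' @return an object of class `genome_index`.
#' @export
build_index <- function(genome, lengths) {
  lengths <- sort(unique(as.integer(lengths)))
  if (length(lengths) == 0L) stopf("lengths must be non-empty")
  seqs <- genome_as_character(genome)
  widths <- chrom_lengths(genome)
  tables <- lapply(lengths, function(L) {
    parts <- lapply(names(seqs), function(ch) {
      n <- widths[[ch]] - L + 1L
      if (n <= 0L) {
        message(sprintf("chromosome %s is shorter than %d bp; no %d-mers indexed",
                        ch, L, L))
        return(NULL)
      }
      starts <- seq_len(n)
      fwd <- substring(seqs[[ch]], starts, starts + L - 1L)
      data.table::data.table(
        kmer = c(fwd, revcomp(fwd)),
        chrom = ch,
        pos = c(starts, starts + L - 1L),
        strand = rep(c("+", "-"), each = n))
    })
    dt <- data.table::rbindlist(parts)
    if (nrow(dt)) data.table::setkey(dt, kmer)
    dt
  })
  names(tables) <- as.character(lengths)
  structure(list(tables = tables, lengths = lengths, widths = widths),
            class = "genome_index")
}

#' Query a genome index with tag sequences
#'
#' @param index a [build_index()] result.
#' @param tags character vector of tag sequences (lengths must be indexed).
#' @return data.frame of hits: tag, chrom, pos (5'-end coordinate in
#'   transcript orientation), strand. Tags without a hit contribute no rows.
#' @export
query_index <- function(index, tags) {
  stopifnot(inherits(index, "genome_index"))
  tags <- unique(tags)
  lens <- nchar(tags)
  missing_len <- setdiff(unique(lens), index$lengths)
  if (length(missing_len)) {
    stopf("index not built for tag length(s): %s",
          paste(missing_len, collapse = ", "))
  }
  parts <- lapply(index$lengths, function(L) {
    q <- tags[lens == L]
    if (length(q) == 0L) return(NULL)
    dt <- index$tables[[as.character(L)]]
    if (nrow(dt) == 0L) return(NULL)
    hits <- dt[data.table::data.table(kmer = q), on = "kmer", nomatch = NULL]
    hits
  })
  out <- data.table::rbindlist(parts)
  if (nrow(out) == 0L) {
    return(data.frame(tag = character(0), chrom = character(0),
                      pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- as.data.frame(out)
  names(out)[names(out) == "kmer"] <- "tag"
  out[order(out$tag, out$chrom, out$pos, out$strand), , drop = FALSE] |>
    `rownames<-`(NULL)
}

MULTIPLICITY_CLASSES <- c("unique", "multi_2_4", "multi_5_10",
                          "multi_11_plus", "unmapped")

multiplicity_class <- function(n_hits) {
  cut(n_hits, breaks = c(-Inf, 0, 1, 4, 10, Inf),
      labels = c("unmapped", "unique", "multi_2_4", "multi_5_10",
                 "multi_11_plus")) |>
    as.character() |>
    factor(levels = MULTIPLICITY_CLASSES)
}

#' Map a tag count table to the genome and classify multiplicity
#'
#' Every distinct tag is matched exactly (no mismatches) against both
#' strands and binned by its number of genomic hits: unique, 2-4, 5-10,
#' >=11, or unmapped. Only uniquely mapping tags are carried into
#' annotation and expression; multi-mapped and unmapped tags are retained
#' in the report but barred from downstream analysis, since they cannot be
#' assigned a single genomic origin. The summary is occurrence-weighted
#' (a tag seen 12 times contributes 12 to its class).
#'
#' @param table a `tag_count_table` from [collapse_and_filter()].
#' @param index a [build_index()] covering all tag lengths in `table`.
#' @return list of class `tag_mapping`: `tag_classes` (tag, count, n_hits,
#'   class), `hits` (all hits for all tags), `unique_hits` (tag, count,
#'   chrom, pos, strand for uniquely mapped tags) and `summary`
#'   (occurrence-weighted class counts and percentages).
#' @export
map_tags <- function(table, index) {
  stopifnot(inherits(table, "tag_count_table"))
  tags <- table$entries$tag
  hits <- query_index(index, tags)
  n_hits <- integer(length(tags))
  if (nrow(hits)) {
    tab <- table(factor(hits$tag, levels = tags))
    n_hits <- as.integer(tab)
  }
  tag_classes <- data.frame(tag = tags, count = table$entries$count,
                            n_hits = n_hits,
                            class = multiplicity_class(n_hits),
                            stringsAsFactors = FALSE)
  uniq <- tag_classes[tag_classes$class == "unique", c("tag", "count")]
  unique_hits <- merge(uniq, hits, by = "tag", sort = TRUE)
  class_counts <- tapply(tag_classes$count,
                         tag_classes$class, sum, default = 0L)
  total <- table$total_valid_tags
  summary <- data.frame(
    class = MULTIPLICITY_CLASSES,
    tag_occurrences = as.integer(class_counts[MULTIPLICITY_CLASSES]),
    stringsAsFactors = FALSE)
  summary$percent <- if (total > 0) 100 * summary$tag_occurrences / total else 0
  structure(list(stage = table$stage, tag_classes = tag_classes,
                 hits = hits, unique_hits = unique_hits,
                 summary = summary, total_valid_tags = total),
            class = "tag_mapping")
}

#' @export
print.tag_mapping <- function(x, ...) {
  cat(sprintf("tag mapping [%s]: %d tag occurrences\n", x$stage,
              x$total_valid_tags))
  print(x$summary)
  invisible(x)
}

#' Library-summary table of mapping multiplicity
#'
#' Combines per-stage mapping summaries into one table in the layout of
#' the study's extraction/mapping summary (total valid tags; unique,
#' multiple 2-4 / 5-10 / >=11, and unmapped occurrences with percentages).
#'
#' @param ... `tag_mapping` objects.
#' @return data.frame with one row per class per stage.
#' @export
mapping_summary <- function(...) {
  maps <- list(...)
  do.call(rbind, lapply(maps, function(m) {
    cbind(stage = m$stage, m$summary,
          total_valid_tags = m$total_valid_tags)
  }))
}
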