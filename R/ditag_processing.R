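#' Quality-filter ditag reads
#'
#' Retains reads whose mean Phred quality is at least `min_mean_q` and
#' whose worst base is at least `min_base_q`. The study screened reads on
#' Phred-equivalent scores without publishing cutoffs; the defaults here
#' (mean >= 20, min >= 10) are conventional for pyrosequencing reads and
#' configurable.
#'
#' @param reads data.frame with columns read_id, sequence, qualities
#'   (Sanger Phred+33 strings), e.g. from [read_fastq()].
#' @param min_mean_q minimum mean quality.
#' @param min_base_q minimum per-base quality.
#' @return list with `reads` (the retained rows) and `stats` (reads in,
#'   retained, dropped by each rule).
#' @export
quality_filter <- function(reads, min_mean_q = 20, min_base_q = 10) {
  if (min_mean_q < 0 || min_base_q < 0) stopf("quality thresholds must be >= 0")
  if (nrow(reads) > 0 && any(nchar(reads$sequence) != nchar(reads$qualities))) {
    bad <- reads$read_id[nchar(reads$sequence) != nchar(reads$qualities)]
    stopf("malformed record(s): %s", paste(bad, collapse = ", "))
  }
  scores <- lapply(reads$qualities, decode_phred)
  mean_ok <- vapply(scores, function(q) mean(q) >= min_mean_q, logical(1))
  base_ok <- vapply(scores, function(q) min(q) >= min_base_q, logical(1))
  keep <- mean_ok & base_ok
  stats <- list(n_in = nrow(reads),
                n_retained = sum(keep),
                n_dropped_mean_q = sum(!mean_ok),
                n_dropped_base_q = sum(mean_ok & !base_ok))
  list(reads = reads[keep, , drop = FALSE], stats = stats)
}

#' Split ditag reads into individual 5' tags
#'
#' Locates the 5' adapter, linker and 3' adapter by exact match (in that
#' order, left to right), reports the first tag as read and the second tag
#' reverse-complemented back to transcript orientation. Reads failing any
#' landmark, or yielding tags outside the layout's length range (including
#' tags containing N, which exact-match mapping cannot use), are returned
#' as invalid with a reason code.
#'
#' @param reads data.frame of quality-filtered reads.
#' @param layout a [ditag_layout()].
#' @return data.frame: read_id, tag1, tag2, valid,
#'   reason (`ok | no_adapter | no_linker | bad_tag_length`).
#' @export
extract_tags <- function(reads, layout) {
  stopifnot(inherits(layout, "ditag_layout"))
  n <- nrow(reads)
  tag1 <- tag2 <- rep(NA_character_, n)
  reason <- rep("ok", n)
  lo <- layout$tag_length_range[1]
  hi <- layout$tag_length_range[2]
  p5 <- regexpr(layout$adapter_5, reads$sequence, fixed = TRUE)
  for (i in seq_len(n)) {
    s <- reads$sequence[i]
    if (p5[i] < 0L) { reason[i] <- "no_adapter"; next }
    from1 <- p5[i] + nchar(layout$adapter_5)
    rest <- substr(s, from1, nchar(s))
    pl <- regexpr(layout$linker, rest, fixed = TRUE)
    if (pl < 0L) { reason[i] <- "no_linker"; next }
    t1 <- substr(rest, 1L, pl - 1L)
    rest2 <- substr(rest, pl + nchar(layout$linker), nchar(rest))
    p3 <- regexpr(layout$adapter_3, rest2, fixed = TRUE)
    if (p3 < 0L) { reason[i] <- "no_adapter"; next }
    t2rc <- substr(rest2, 1L, p3 - 1L)
    if (nchar(t1) < lo || nchar(t1) > hi || nchar(t2rc) < lo ||
        nchar(t2rc) > hi || !all(is_dna(c(t1, t2rc), allow_n = FALSE))) {
      reason[i] <- "bad_tag_length"
      next
    }
    tag1[i] <- t1
    tag2[i] <- revcomp(t2rc)
  }
  data.frame(read_id = reads$read_id, tag1 = tag1, tag2 = tag2,
             valid = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Collapse extracted tags into a count table
#'
#' Sums identical tag sequences and, following the study's tag-extraction
#' stage, optionally discards singleton tags (count 1) at the library
#' level before mapping.
#'
#' @param tags character vector of tag occurrences (e.g. `c(t$tag1, t$tag2)`
#'   over the valid rows of [extract_tags()] output).
#' @param stage library label, e.g. `"Myc"` or `"S1-Pri"`.
#' @param drop_singletons discard tags seen exactly once.
#' @return an object of class `tag_count_table`: list with `stage`,
#'   `entries` (data.frame tag, count), `total_valid_tags` (sum of retained
#'   counts) and `n_singletons_dropped`.
#' @export
collapse_and_filter <- function(tags, stage, drop_singletons = TRUE) {
  tags <- tags[!is.na(tags)]
  tab <- table(tags)
  entries <- data.frame(tag = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  n_singletons <- 0L
  if (drop_singletons) {
    n_singletons <- sum(entries$count == 1L)
    entries <- entries[entries$count > 1L, , drop = FALSE]
  }
  entries <- entries[order(entries$tag), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(stage = stage, entries = entries,
                 total_valid_tags = sum(entries$count),
                 n_singletons_dropped = n_singletons),
            class = "tag_count_table")
}

#' @export
print.tag_count_table <- function(x, ...) {
  cat(sprintf("tag count table [%s]: %d distinct tags, %d occurrences (%d singletons dropped)\n",
              x$stage, nrow(x$entries), x$total_valid_tags,
              x$n_singletons_dropped))
  invisible(x)
}

#' Write a tag count table to TSV
#' @param table a `tag_count_table`.
#' @param path output file (columns tag, count).
#' @return `path`, invisibly.
#' @export
write_tag_table <- function(table, path) {
  utils::write.table(table$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a tag count table from TSV
#' @param path TSV with columns tag, count.
#' @param stage library label to attach.
#' @return a `tag_count_table`.
#' @export
read_tag_table <- function(path, stage) {
  entries <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tag", "count") %in% names(entries)))
  structure(list(stage = stage, entries = entries,
                 total_valid_tags = sum(entries$count),
                 n_singletons_dropped = NA_integer_),
            class = "tag_count_table")
}

#' Run the full tag-extraction stage on one library
#'
#' Quality filtering, ditag splitting and collapsing in one call, with a
#' processing-stats report in the style of the study's extraction summary.
#'
#' @param reads raw read data.frame (see [read_fastq()]).
#' @param layout a [ditag_layout()].
#' @param stage library label.
#' @param min_mean_q,min_base_q quality thresholds, see [quality_filter()].
#' @param drop_singletons see [collapse_and_filter()].
#' @return list with `table` (a `tag_count_table`), `tags` (per-read tag
#'   data.frame) and `stats` (named list of stage counts).
#' @export
process_library <- function(reads, layout, stage, min_mean_q = 20,
                            min_base_q = 10, drop_singletons = TRUE) {
  qf <- quality_filter(reads, min_mean_q, min_base_q)
  ext <- extract_tags(qf$reads, layout)
  valid <- ext[ext$valid, , drop = FALSE]
  occ <- c(rbind(valid$tag1, valid$tag2))  # interleaved: 2 per ditag
  table <- collapse_and_filter(occ, stage, drop_singletons)
  stats <- c(qf$stats,
             list(n_valid_ditags = nrow(valid),
                  n_invalid_ditags = sum(!ext$valid),
                  invalid_reasons = as.list(table(ext$reason[!ext$valid])),
                  n_tag_occurrences = length(occ),
                  n_singletons_dropped = table$n_singletons_dropped,
                  total_valid_tags = table$total_valid_tags))
  list(table = table, tags = ext, stats = stats)
}
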