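CATEGORY_LEVELS <- c("utr5_sense", "cds_sense", "utr3_sense",
                     "utr5_antisense", "cds_antisense", "utr3_antisense",
                     "unclassified")

# Derive the classification windows of every gene: the putative 5'-UTR is
# the 500 bases immediately upstream of the start codon (offsets -500..-1
# in transcript orientation), the coding span, and the putative 3'-UTR the
# 500 bases downstream of the stop codon (+1..+500). Windows are clipped at
# chromosome ends and keep their category.
gene_windows <- function(models, chrom_len) {
  if (nrow(models) == 0L) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), region = character(0),
                      start = integer(0), end = integer(0),
                      coding_start = integer(0), coding_end = integer(0)))
  }
  plus <- models$strand == "+"
  w <- function(region, start, end) {
    data.frame(gene_id = models$gene_id, chrom = models$chrom,
               strand = models$strand, region = region,
               start = start, end = end,
               coding_start = models$coding_start,
               coding_end = models$coding_end, stringsAsFactors = FALSE)
  }
  utr5 <- w("utr5",
            ifelse(plus, models$coding_start - UTR_WINDOW, models$coding_start + 1L),
            ifelse(plus, models$coding_start - 1L, models$coding_start + UTR_WINDOW))
  cds <- w("cds", models$gene_left, models$gene_right)
  utr3 <- w("utr3",
            ifelse(plus, models$coding_end + 1L, models$coding_end - UTR_WINDOW),
            ifelse(plus, models$coding_end + UTR_WINDOW, models$coding_end - 1L))
  out <- rbind(utr5, cds, utr3)
  lens <- chrom_len[out$chrom]
  out$start <- pmax(out$start, 1L)
  out$end <- pmin(out$end, as.integer(lens))
  out[out$start <= out$end, , drop = FALSE]
}

#' Classify genome positions of tags relative to gene models
#'
#' Assigns each uniquely mapped tag position one of seven categories:
#' sense or antisense combinations of the putative 5'-UTR window
#' (-500..-1 relative to the start codon), the coding span, and the
#' putative 3'-UTR window (+1..+500 relative to the stop codon), or
#' unclassified. Sense means the tag strand equals the gene strand. When a
#' position falls into windows of several genes, the category priority is
#' utr5_sense > cds_sense > utr3_sense > utr5_antisense > cds_antisense >
#' utr3_antisense, with the nearest start codon breaking remaining ties.
#'
#' @param hits data.frame with columns chrom, pos (5'-end coordinate in
#'   transcript orientation), strand; extra columns are carried through.
#' @param models gene-model data.frame.
#' @param chrom_len named vector of chromosome lengths (see
#'   [chrom_lengths()] via a genome object), used to clip windows.
#' @return `hits` with added columns category (factor over the seven
#'   levels), gene_id (NA when unclassified) and offset (signed bases
#'   relative to the start codon for 5'-UTR/CDS or to the stop codon for
#'   3'-UTR, in transcript orientation; NA when unclassified).
#' @export
classify_hits <- function(hits, models, chrom_len) {
  n <- nrow(hits)
  category <- rep("unclassified", n)
  gene_id <- rep(NA_character_, n)
  offset <- rep(NA_integer_, n)
  win <- gene_windows(models, chrom_len)
  if (n > 0L && nrow(win) > 0L) {
    for (ch in unique(hits$chrom)) {
      hi <- which(hits$chrom == ch)
      wi <- which(win$chrom == ch)
      if (length(wi) == 0L) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(hits$pos[hi], width = 1L),
        IRanges::IRanges(win$start[wi], win$end[wi]))
      if (length(ov) == 0L) next
      qh <- hi[S4Vectors::queryHits(ov)]
      wh <- wi[S4Vectors::subjectHits(ov)]
      sense <- hits$strand[qh] == win$strand[wh]
      rank <- match(win$region[wh], c("utr5", "cds", "utr3")) +
        ifelse(sense, 0L, 3L)
      dist <- abs(hits$pos[qh] - win$coding_start[wh])
      ord <- order(qh, rank, dist, win$gene_id[wh])
      first <- ord[!duplicated(qh[ord])]
      idx <- qh[first]
      category[idx] <- paste0(win$region[wh[first]],
                              ifelse(sense[first], "_sense", "_antisense"))
      gene_id[idx] <- win$gene_id[wh[first]]
      plus <- win$strand[wh[first]] == "+"
      anchor <- ifelse(win$region[wh[first]] == "utr3",
                       win$coding_end[wh[first]],
                       win$coding_start[wh[first]])
      offset[idx] <- ifelse(plus, hits$pos[idx] - anchor,
                            anchor - hits$pos[idx])
    }
  }
  hits$category <- factor(category, levels = CATEGORY_LEVELS)
  hits$gene_id <- gene_id
  hits$offset <- offset
  hits
}

#' Annotate a uniquely mapped library against gene models
#'
#' Classifies every unique tag hit and reports occurrence-weighted counts
#' per category; the seven categories partition the uniquely mapped total
#' exactly.
#'
#' @param unique_hits data.frame with columns tag, count, chrom, pos,
#'   strand (the `unique_hits` element of [map_tags()]).
#' @param models gene-model data.frame.
#' @param chrom_len named chromosome lengths.
#' @param stage library label attached to the summary.
#' @return list of class `library_annotation`: `classified` (per-tag
#'   classification with counts) and `summary` (category, tag_occurrences,
#'   percent over the uniquely mapped total).
#' @export
annotate_library <- function(unique_hits, models, chrom_len, stage = NA) {
  classified <- classify_hits(unique_hits, models, chrom_len)
  total <- sum(classified$count)
  occ <- tapply(classified$count, classified$category, sum, default = 0L)
  summary <- data.frame(category = CATEGORY_LEVELS,
                        tag_occurrences = as.integer(occ[CATEGORY_LEVELS]),
                        stringsAsFactors = FALSE)
  summary$percent <- if (total > 0) 100 * summary$tag_occurrences / total else 0
  structure(list(stage = stage, classified = classified, summary = summary,
                 total_unique_mapped = total),
            class = "library_annotation")
}

#' @export
print.library_annotation <- function(x, ...) {
  cat(sprintf("library annotation [%s]: %d uniquely mapped occurrences\n",
              if (is.na(x$stage)) "?" else x$stage, x$total_unique_mapped))
  print(x$summary)
  invisible(x)
}

#' Build per-gene TSS catalogues from 5'-UTR sense tags
#'
#' Aggregates utr5_sense tag occurrences into per-gene arrays of TSS
#' coordinates. Genes typically present an array of start sites with one
#' or two preferred TSSs; operationally, the top-count site is always
#' preferred and the runner-up is added when its count reaches at least
#' half of the top count. Coordinate ties rank deterministically.
#'
#' @param classified classification data.frame (the `classified` element
#'   of [annotate_library()], or any frame with category, gene_id, pos,
#'   count).
#' @return data.frame with one row per (gene, TSS): gene_id, tss, count,
#'   preferred.
#' @export
build_tss_catalogs <- function(classified) {
  u5 <- classified[classified$category == "utr5_sense", , drop = FALSE]
  if (nrow(u5) == 0L) {
    return(data.frame(gene_id = character(0), tss = integer(0),
                      count = integer(0), preferred = logical(0)))
  }
  agg <- stats::aggregate(count ~ gene_id + pos, data = u5, FUN = sum)
  names(agg)[names(agg) == "pos"] <- "tss"
  agg <- agg[order(agg$gene_id, -agg$count, agg$tss), , drop = FALSE]
  parts <- split(agg, agg$gene_id)
  out <- do.call(rbind, lapply(parts, function(g) {
    g$preferred <- FALSE
    g$preferred[1] <- TRUE
    if (nrow(g) >= 2L && g$count[2] * 2L >= g$count[1]) g$preferred[2] <- TRUE
    g
  }))
  rownames(out) <- NULL
  out[, c("gene_id", "tss", "count", "preferred")]
}

#' Export TSS positions as a BED track
#'
#' @param catalog data.frame from [build_tss_catalogs()].
#' @param classified the classification frame the catalogue came from
#'   (supplies chrom and strand per gene).
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(catalog, classified, path) {
  u5 <- unique(classified[classified$category == "utr5_sense",
                          c("gene_id", "chrom", "pos", "strand")])
  m <- merge(catalog, u5, by.x = c("gene_id", "tss"),
             by.y = c("gene_id", "pos"))
  bed <- data.frame(chrom = m$chrom, start = m$tss - 1L, end = m$tss,
                    name = paste0(m$gene_id, ifelse(m$preferred, "|preferred", "")),
                    score = m$count, strand = m$strand)
  bed <- bed[order(bed$chrom, bed$start), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
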