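#!/usr/bin/env Rscript
# Quality-filter the raw ditag reads, split every valid ditag into its two
# 5' tags, collapse to per-library count tables and discard singletons --
# the tag-extraction stage. Writes the tag tables and an extraction-stats
# report (the header rows of a library summary).

suppressMessages(library(sagetag))
outdir <- "results/run"
layout <- ditag_layout()

stats <- list()
for (s in c("Myc", "S1-Pri")) {
  reads <- read_fastq(file.path(outdir, sprintf("reads_%s.fastq", s)))
  lib <- process_library(reads, layout, s, min_mean_q = 20, min_base_q = 10,
                         drop_singletons = TRUE)
  write_tag_table(lib$table, file.path(outdir, sprintf("tags_%s.tsv", s)))
  stats[[s]] <- lib$stats
  cat(sprintf("%s: %d reads in, %d retained, %d valid ditags, %d tag occurrences, %d singletons dropped -> %d valid tags\n",
              s, lib$stats$n_in, lib$stats$n_retained,
              lib$stats$n_valid_ditags, lib$stats$n_tag_occurrences,
              lib$stats$n_singletons_dropped, lib$stats$total_valid_tags))
}
jsonlite::write_json(stats, file.path(outdir, "extraction_stats.json"),
                     auto_unbox = TRUE, pretty = TRUE)
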