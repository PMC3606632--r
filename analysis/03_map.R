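#!/usr/bin/env Rscript
# Map every distinct tag to the toy genome by exact match on both strands
# and bin tags by mapping multiplicity (unique / 2-4 / 5-10 / >=11 /
# unmapped). Only uniquely mapped tags continue into annotation; the
# occurrence-weighted class summary mirrors the library mapping table.

suppressMessages(library(sagetag))
outdir <- "results/run"

genome <- Biostrings::readDNAStringSet(file.path(outdir, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))

tables <- lapply(c(Myc = "Myc", `S1-Pri` = "S1-Pri"), function(s) {
  read_tag_table(file.path(outdir, sprintf("tags_%s.tsv", s)), s)
})
lens <- sort(unique(nchar(unlist(lapply(tables, function(t) t$entries$tag)))))
index <- build_index(genome, lens)

maps <- lapply(tables, function(t) map_tags(t, index))
for (s in names(maps)) {
  write.table(maps[[s]]$unique_hits,
              file.path(outdir, sprintf("hits_%s.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  u <- maps[[s]]$summary
  cat(sprintf("%s: %d occurrences; unique %.1f%%, multi %.1f%%, unmapped %.1f%%\n",
              s, maps[[s]]$total_valid_tags,
              u$percent[u$class == "unique"],
              sum(u$percent[grepl("multi", u$class)]),
              u$percent[u$class == "unmapped"]))
}
write.table(do.call(mapping_summary, unname(maps)),
            file.path(outdir, "mapping_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
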