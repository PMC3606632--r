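#!/usr/bin/env Rscript
# Classify uniquely mapped tags against the gene models -- sense/antisense
# x 5'-UTR/CDS/3'-UTR windows -- and build per-gene TSS catalogues with
# preferred start sites. The category summary mirrors the gene-associated
# position table of a 5'-SAGE study.

suppressMessages(library(sagetag))
outdir <- "results/run"

genome <- Biostrings::readDNAStringSet(file.path(outdir, "genome.fa"))
names(genome) <- sub(" .*", "", names(genome))
lens <- setNames(Biostrings::width(genome), names(genome))
models <- read_models_gff3(file.path(outdir, "models.gff3"))

anns <- lapply(c(Myc = "Myc", `S1-Pri` = "S1-Pri"), function(s) {
  hits <- read.delim(file.path(outdir, sprintf("hits_%s.tsv", s)))
  ann <- annotate_library(hits, models, lens, stage = s)
  write.table(ann$classified,
              file.path(outdir, sprintf("classification_%s.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  u5 <- ann$summary$percent[ann$summary$category == "utr5_sense"]
  anti <- sum(ann$summary$percent[grepl("antisense", ann$summary$category)])
  cat(sprintf("%s: %d uniquely mapped occurrences; %.1f%% 5'-UTR sense, %.1f%% antisense\n",
              s, ann$total_unique_mapped, u5, anti))
  ann
})
write.table(do.call(rbind, lapply(anns, function(a) cbind(stage = a$stage, a$summary))),
            file.path(outdir, "category_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

all_class <- do.call(rbind, lapply(anns, `[[`, "classified"))
catalog <- build_tss_catalogs(all_class)
write.table(catalog, file.path(outdir, "tss_catalog.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_tss_bed(catalog, all_class, file.path(outdir, "tss_sites.bed"))
cat(sprintf("TSS catalogue: %d sites over %d genes, %d preferred\n",
            nrow(catalog), length(unique(catalog$gene_id)),
            sum(catalog$preferred)))
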