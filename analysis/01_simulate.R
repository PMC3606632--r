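#!/usr/bin/env Rscript
# Generate the synthetic study: a toy gene-dense genome, two-stage
# expression truth with a designated DEG subset, and two ditag libraries
# of unequal depth (the deeper one for the primordium stage, as in the
# source libraries). Everything downstream works from the files written
# here.

suppressMessages(library(sagetag))
outdir <- "results/run"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20130320L

spec <- genome_spec(seed = seed)          # 3 x 35 kb, 30 genes
gen <- generate_genome(spec)
truths <- simulate_truth(gen$models, deg_fraction = 1/3,
                         fold_range = c(3, 8), seed = seed + 1L)
layout <- ditag_layout()
sim <- simulate_reads(gen$genome, gen$models, truths, layout,
                      n_reads_per_stage = c(2000L, 3000L),
                      error_rate = 0.005, seed = seed + 2L)

write_genome_fasta(gen$genome, file.path(outdir, "genome.fa"))
write_models_gff3(gen$models, gen$genome, file.path(outdir, "models.gff3"))
for (s in names(sim$reads)) {
  write_fastq(sim$reads[[s]], file.path(outdir, sprintf("reads_%s.fastq", s)))
}
write.table(sim$truth, file.path(outdir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
gene_truth <- truths[, setdiff(names(truths), "tss_profile")]
gene_truth$tss_profile <- vapply(truths$tss_profile, function(p) {
  paste(sprintf("-%d:%.2f", p$offset, p$weight), collapse = ";")
}, character(1))
write.table(gene_truth, file.path(outdir, "truth_genes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("genome: %d chromosomes x %d bp, %d genes (%d DEGs by design)\n",
            spec$n_chromosomes, spec$chromosome_length, nrow(gen$models),
            sum(truths$is_deg)))
cat(sprintf("reads: %s\n", paste(sprintf("%s=%d", names(sim$reads),
                                         vapply(sim$reads, nrow, 0L)),
                                 collapse = ", ")))
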