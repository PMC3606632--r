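#!/usr/bin/env Rscript
# Domain enrichment and lineage-specificity classification of the DEG
# sets. Real runs consume external domain assignments and homology
# reports; here both are synthetic fixtures constructed over the toy gene
# set (written next to the outputs, labelled synthetic), so the stage
# demonstrates the statistics, not a biological claim.

suppressMessages(library(sagetag))
outdir <- "results/run"
set.seed(42)

expr <- read.delim(file.path(outdir, "expression.tsv"))
models <- read_models_gff3(file.path(outdir, "models.gff3"))
universe <- models$gene_id

# Synthetic domain table: a handful of domain families scattered over the
# universe, one family deliberately concentrated in the Myc-up DEGs.
deg_myc <- expr$gene_id[expr$deg_direction == "myc_up"]
deg_pri <- expr$gene_id[expr$deg_direction == "pri_up"]
asg <- data.frame(
  orf_id = c(sample(universe, 12, replace = TRUE), deg_myc),
  domain_id = c(sample(c("PF_kinase", "PF_transporter", "PF_ribosomal"),
                       12, replace = TRUE),
                rep("PF_hydrophobin_like", length(deg_myc))),
  e_value = 1e-30)
write.table(asg, file.path(outdir, "domains_synthetic.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

enr <- rbind(
  if (length(deg_myc)) cbind(deg_set = "myc_up",
                             domain_enrichment(asg, deg_myc, universe)),
  if (length(deg_pri)) cbind(deg_set = "pri_up",
                             domain_enrichment(asg, deg_pri, universe)))
write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("domain enrichment: %d tests, %d enriched (p < 0.05)\n",
            nrow(enr), sum(enr$enriched)))
print(enr[enr$enriched, c("deg_set", "domain_id", "k_deg", "k_all", "p_value")])

# Synthetic per-species best hits: half the DEGs get strong hits in two
# fruiting-body formers only, a quarter get an outgroup hit as well.
fbf <- c("Lbic", "Pchr", "Ppla", "Scom", "Post", "Abis", "Ledo")
outg <- c("Scer", "Cneo", "Umay", "Afum")
degs <- c(deg_myc, deg_pri)
hits <- do.call(rbind, lapply(seq_along(degs), function(i) {
  r <- i %% 4
  if (r == 0) NULL                                   # no hits: species-unique
  else if (r == 1) data.frame(gene_id = degs[i],     # basidiomycete-unique
                              species = sample(fbf, 3),
                              e_value = 10^-runif(3, 15, 60))
  else if (r == 2) data.frame(gene_id = degs[i],     # broadly conserved
                              species = c(sample(fbf, 2), sample(outg, 1)),
                              e_value = 10^-runif(3, 15, 60))
  else data.frame(gene_id = degs[i],                 # one weak FBF hit
                  species = sample(fbf, 1), e_value = 10^-runif(1, 3, 8))
}))
write.table(hits, file.path(outdir, "homology_hits_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lin <- classify_lineage(degs, hits, fbf, outg)
write.table(lin, file.path(outdir, "lineage.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("lineage classes:\n")
print(table(lin$classification))
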