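#!/usr/bin/env Rscript
# Quantify per-gene expression as tags per 100,000 of the uniquely
# genome-mapped total, call differential expression with the pairwise
# Fisher exact test at unadjusted p < 0.05, and compare the calls with
# the designed truth.

suppressMessages(library(sagetag))
outdir <- "results/run"

cls <- lapply(c(Myc = "Myc", `S1-Pri` = "S1-Pri"), function(s) {
  df <- read.delim(file.path(outdir, sprintf("classification_%s.tsv", s)))
  df$category <- factor(df$category, levels = sagetag:::CATEGORY_LEVELS)
  df
})
totals <- vapply(cls, function(df) sum(df$count), 0)

counts <- gene_counts(cls[["Myc"]], cls[["S1-Pri"]])
expr <- quantify(counts, totals[["Myc"]], totals[["S1-Pri"]])
de <- call_degs(expr, totals[["Myc"]], totals[["S1-Pri"]], de_config())
write.table(de$genes, file.path(outdir, "expression.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(de$summary, file.path(outdir, "deg_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("assessed %d genes; %d DEGs (%d Myc-up, %d S1-Pri-up)\n",
            de$n_assessed, sum(de$genes$is_deg),
            sum(de$genes$deg_direction == "myc_up"),
            sum(de$genes$deg_direction == "pri_up")))

truth <- read.delim(file.path(outdir, "truth_genes.tsv"))
g <- merge(de$genes, truth[, c("gene_id", "is_deg", "true_log2_fold")],
           by = "gene_id", suffixes = c("", "_true"))
tp <- sum(g$is_deg & g$is_deg_true); fp <- sum(g$is_deg & !g$is_deg_true)
cat(sprintf("against the design: %d/%d true DEGs recovered, %d false positives\n",
            tp, sum(g$is_deg_true), fp))
err <- abs(g$log2_ratio - g$true_log2_fold)[g$is_deg & g$is_deg_true]
if (length(err)) {
  cat(sprintf("median |log2 ratio error| over recovered DEGs: %.2f\n",
              median(err)))
}
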