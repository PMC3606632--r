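#!/usr/bin/env Rscript
# Cross-platform agreement: Pearson correlations between the 5'-SAGE log2
# ratios and the microarray / real-time RT-PCR log2 ratios of the
# packaged 18-gene panel.

suppressMessages(library(sagetag))
outdir <- "results/run"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

panel <- validation_panel()
rep <- validate_report(panel)
print(rep)
jsonlite::write_json(rep$correlations, file.path(outdir, "validation.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("panel of %d genes; SAGE~qPCR r = %.3f, SAGE~microarray r = %.3f\n",
            nrow(panel),
            rep$correlations$r[rep$correlations$pair == "sage_vs_qpcr"],
            rep$correlations$r[rep$correlations$pair == "sage_vs_microarray"]))
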