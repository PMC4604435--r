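#!/usr/bin/env Rscript
# Rule-based reconstruction of the in vitro processing assay: every
# printed substrate against whole-cell and EV protein extracts. Writes
# results/processing_panel.tsv.

suppressPackageStartupMessages(library(evrny5))
dir.create("results", showWarnings = FALSE)

panel <- processing_panel()
write_tsv_file(panel, "results/processing_panel.tsv")
print(as.data.frame(panel))

message("Whole-cell extracts leave every substrate intact; EV extracts cut the motif-bearing 83-mer into all processed forms (23/29/31 nt) and the 31-mer into the 23-nt product; scrambling the motif leaves only residual 23-nt processing, and fully scrambled or double-stranded substrates are untouched.")
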