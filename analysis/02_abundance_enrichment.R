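#!/usr/bin/env Rscript
# Simulates the four packaged libraries (BJ / K562, whole-cell / EV) at
# one million reads each, runs the aligner and union-mode counting, and
# tabulates RNA-family abundance, EV-versus-cell enrichment of RNY5, and
# per-gene EV/(EV+cell) ratios. Writes per-library count and family TSVs
# plus enrichment summaries under results/.

suppressPackageStartupMessages(library(evrny5))
dir.create("results", showWarnings = FALSE)

N_READS <- 1e6   # matches the scale at which the headline shares are quoted
SEED <- 20150

ref <- build_reference()
write_reference(ref, "results/reference.fa", "results/annotations.bed")
profiles <- default_library_profiles(ref, read_count = N_READS)

counts <- list()
for (nm in names(profiles)) {
  message("simulating + aligning ", nm, " ...")
  sim <- simulate_library(profiles[[nm]], ref, seed = SEED + match(nm, names(profiles)))
  aln <- align_reads(sim, ref)
  ct <- count_genes(aln, ref, library_id = nm)
  counts[[nm]] <- ct
  write_tsv_file(ct, sprintf("results/%s.counts.tsv", nm))
  write_tsv_file(family_table(ct), sprintf("results/%s.families.tsv", nm))
}

summ <- do.call(rbind, lapply(names(counts), function(nm) {
  ct <- counts[[nm]]
  fam <- family_table(ct)
  data.frame(library = nm,
             rny5_pct_of_assigned = 100 * ct$rpm[ct$gene_id == "RNY5"] / sum(ct$rpm),
             rny5_pct_of_miscRNA = 100 * ct$rpm[ct$gene_id == "RNY5"] /
               fam$rpm[fam$family == "miscRNA"],
             total_unique = attr(ct, "total_unique"),
             multimapper_records = attr(ct, "n_multimapper"))
}))
write_tsv_file(summ, "results/library_summary.tsv")
print(summ)

enr <- do.call(rbind, lapply(c("bj", "k562"), function(line) {
  ev <- counts[[paste0(line, "_ev")]]
  cell <- counts[[paste0(line, "_cell")]]
  write_tsv_file(ev_cell_ratio(ev, cell),
                 sprintf("results/%s.ev_cell_ratio.tsv", line))
  data.frame(cell_line = line,
             rny5_fold = enrichment(ev, cell, "RNY5"),
             rny5_ev_ratio = ev_cell_ratio(ev, cell)$ratio[
               ev_cell_ratio(ev, cell)$gene_id == "RNY5"])
}))
write_tsv_file(enr, "results/rny5_enrichment.tsv")
print(enr)

message(sprintf(
  "RNY5 dominates the EV libraries (%.1f%% / %.1f%% of assigned reads; >%.0f%% of miscRNA) while staying a trace component of whole cells; the paired fold-enrichments land near the 196x (BJ) and 68x (K562) anchors.",
  summ$rny5_pct_of_assigned[summ$library == "bj_ev"],
  summ$rny5_pct_of_assigned[summ$library == "k562_ev"],
  min(summ$rny5_pct_of_miscRNA[grepl("_ev", summ$library)])))
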