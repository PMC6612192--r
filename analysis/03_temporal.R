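#!/usr/bin/env Rscript
# Temporal trend analysis: the year-over-year weighted Jaccard similarity
# series, phase segmentation with the trough heuristic, the phase table
# over the detected phases, and the rename-event signature.

suppressPackageStartupMessages(library(kwtrends))

if (!file.exists("scratch/annual_matrix.tsv")) {
  stop("run analysis/02_matrix.R first")
}
m <- read_annual_matrix("scratch/annual_matrix.tsv")

series <- similarity_series(m)
write.table(series, "results/03_similarity_series.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

phases <- segment_phases(series)
message("detected phases (trough heuristic, delta=0.1, L=3):")
for (i in seq_len(nrow(phases))) {
  message(sprintf("  phase %d: %d-%d", i, phases$start[i], phases$end[i]))
}

pt <- phase_aggregate(m, phases)
write.table(
  data.frame(keyword = rownames(pt$counts), pt$counts,
             check.names = FALSE),
  "results/03_phase_table.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)

# the planted rename: old label collapses, replacement rises
sig <- rename_signature(pt, "easternmedicine", "nationalmedicine")
message("rename signature (easternmedicine -> nationalmedicine): ", sig)

# the published handover pair shows the same signature in the shipped
# reference table
ref <- oasis_phase_counts()
refm <- as.matrix(ref$counts[, -1])
rownames(refm) <- normalize_keyword(ref$counts$keyword)
ref_pt <- structure(list(counts = refm, article_totals = ref$article_totals,
                         phases = ref$phases), class = "phase_table")
message("reference handover signature (oriental -> korean medicine): ",
        rename_signature(ref_pt, "orientalmedicine", "koreanmedicine"))
message("wrote results/03_similarity_series.tsv, results/03_phase_table.tsv")
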