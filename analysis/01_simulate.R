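#!/usr/bin/env Rscript
# Generate the study-scale synthetic corpus: 29,876 articles over
# 1963-2018 with four planted co-trend keyword groups (stable, late-
# emerging, early-declining, mid-period pulse), synonym variants, and a
# terminology rename in 2012. Writes the corpus and synonym map to
# scratch/ (large, regenerable) and a ground-truth summary to results/.

suppressPackageStartupMessages(library(kwtrends))

dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- corpus_config()
gen <- generate_corpus(cfg, seed = 1)

write_corpus(gen$articles, "scratch/synthetic_corpus.csv")
writeLines(paste(names(gen$synonyms), gen$synonyms, sep = "\t"),
           "scratch/synthetic_synonyms.tsv")
write.table(
  data.frame(token = names(gen$truth$groups),
             group = unname(gen$truth$groups)),
  "results/01_ground_truth_groups.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf("corpus: %d articles, %d-%d", nrow(gen$articles),
                cfg$years[1], cfg$years[2]))
message(sprintf("concepts: %d (in %d groups) + rename pair %s -> %s (%d)",
                length(gen$truth$groups) - 2, length(cfg$groups),
                gen$truth$rename$old, gen$truth$rename$new,
                gen$truth$rename$year))
message("wrote scratch/synthetic_corpus.csv, scratch/synthetic_synonyms.tsv")
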