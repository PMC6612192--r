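#!/usr/bin/env Rscript
# Build the annual keyword-frequency matrix from the simulated corpus
# (normalization + synonym merge + article-level dedup + the >= 10
# frequency filter) and rank the keywords, mirroring the frequency table
# of the reference study.

suppressPackageStartupMessages(library(kwtrends))

if (!file.exists("scratch/synthetic_corpus.csv")) {
  stop("run analysis/01_simulate.R first")
}
articles <- read_corpus("scratch/synthetic_corpus.csv")
map <- load_synonym_map("scratch/synthetic_synonyms.tsv")

m <- build_annual_matrix(articles, map, min_freq = 10)
write_annual_matrix(m, "scratch/annual_matrix.tsv")

top <- top_keywords(m, 30)
write.table(top, "results/02_top_keywords.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf("matrix: %d keywords x %d years from %d articles",
                nrow(m$counts), length(m$years), m$n_articles))
message(sprintf("most frequent keyword: %s (%d articles)",
                top$keyword[1], top$frequency[1]))
message("wrote scratch/annual_matrix.tsv, results/02_top_keywords.tsv")
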