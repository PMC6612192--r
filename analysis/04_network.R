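#!/usr/bin/env Rscript
# Co-trend network and MCL clustering with the reference thresholds
# (node frequency >= 100, edge similarity >= 0.57; MCL expansion 2,
# inflation 2.0, pruning 0.02). Exports the network for Gephi and the
# cluster membership table.

suppressPackageStartupMessages({
  library(kwtrends)
  library(igraph)
})

if (!file.exists("scratch/annual_matrix.tsv")) {
  stop("run analysis/02_matrix.R first")
}
m <- read_annual_matrix("scratch/annual_matrix.tsv")

g <- build_cotrend_network(m, min_freq = 100, min_sim = 0.57)
message(sprintf("network: %d nodes, %d edges", vcount(g), ecount(g)))

export_network(g, "results/04_network.gexf", "gexf")
export_network(g, "scratch/network.graphml", "graphml")

cl <- mcl_cluster(g, mcl_params())
print(cl)
write.table(
  data.frame(keyword = names(cl$labels), cluster = unname(cl$labels)),
  "results/04_clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/04_network.gexf, results/04_clusters.tsv")
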