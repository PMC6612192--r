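# Random weighted undirected graph on n named nodes; edge probability p,
# weights uniform on (0.2, 1].
random_weighted_graph <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    nm <- sprintf("n%02d", seq_len(n))
    pairs <- utils::combn(nm, 2)
    keep <- stats::runif(ncol(pairs)) < p
    el <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                     weight = 0.2 + 0.8 * stats::runif(sum(keep)),
                     stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(
      el, directed = FALSE,
      vertices = data.frame(name = nm, frequency = 100L))
  })
}

# Fixed fixture set of small graphs (<= 6 nodes) for oracle agreement:
# structured motifs plus seeded random graphs.
small_graph_fixtures <- function() {
  g_from_edges <- function(edges, nodes) {
    igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = nodes, frequency = 100L))
  }
  fixtures <- list(
    isolated = g_from_edges(
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0)), "a"),
    pair = g_from_edges(
      data.frame(from = "a", to = "b", weight = 0.9), c("a", "b")),
    triangle = g_from_edges(
      data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                 weight = 1), c("a", "b", "c")),
    path4 = g_from_edges(
      data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                 weight = c(1, 0.2, 1)), letters[1:4]),
    star5 = g_from_edges(
      data.frame(from = "a", to = c("b", "c", "d", "e"), weight = 0.8),
      letters[1:5]),
    two_cliques = g_from_edges(
      data.frame(from = c("a", "a", "b", "d", "d", "e"),
                 to = c("b", "c", "c", "e", "f", "f"), weight = 1),
      letters[1:6]),
    bridged_triangles = g_from_edges(
      data.frame(from = c("a", "a", "b", "d", "d", "e", "c"),
                 to = c("b", "c", "c", "e", "f", "f", "d"),
                 weight = c(1, 1, 1, 1, 1, 1, 0.1)),
      letters[1:6]),
    clique_plus_isolate = g_from_edges(
      data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                 weight = 0.7), letters[1:4])
  )
  for (s in 1:30) {
    n <- 2 + (s %% 5)  # 2..6 nodes
    fixtures[[paste0("random", s)]] <- random_weighted_graph(n, 0.5, seed = s)
  }
  fixtures
}
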