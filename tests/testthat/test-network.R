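mat_from_counts <- function(counts, years) {
  structure(list(
    counts = counts, years = years, min_freq = 1L,
    n_articles = sum(counts),
    articles_per_year = stats::setNames(colSums(counts),
                                        as.character(years))
  ), class = "annual_matrix")
}

test_that("co-trend network applies closed thresholds and keeps isolates", {
  counts <- rbind(a = c(5L, 5L, 0L), b = c(5L, 5L, 0L), c = c(0L, 0L, 9L))
  colnames(counts) <- 2000:2002
  m <- mat_from_counts(counts, 2000:2002)

  g <- build_cotrend_network(m, min_freq = 1, min_sim = 0.9)
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 1)     # identical non-zero rows
  # isolated qualifying node retained
  expect_true("c" %in% igraph::V(g)$name)

  # disjoint year support: nodes present, no edges
  counts2 <- rbind(a = c(5L, 0L), b = c(0L, 5L))
  colnames(counts2) <- 2000:2001
  g2 <- build_cotrend_network(mat_from_counts(counts2, 2000:2001),
                              min_freq = 1, min_sim = 0.1)
  expect_equal(igraph::vcount(g2), 2)
  expect_equal(igraph::ecount(g2), 0)

  # node frequency filter
  g3 <- build_cotrend_network(m, min_freq = 10, min_sim = 0.5)
  expect_setequal(igraph::V(g3)$name, c("a", "b"))

  # edge threshold is closed (>=)
  counts4 <- rbind(a = c(1L, 2L), b = c(2L, 4L))  # J = 0.5 exactly
  colnames(counts4) <- 2000:2001
  g4 <- build_cotrend_network(mat_from_counts(counts4, 2000:2001),
                              min_freq = 1, min_sim = 0.5)
  expect_equal(igraph::ecount(g4), 1)
})

test_that("edge weights equal recomputed pairwise weighted Jaccard", {
  withr::with_seed(13, {
    for (rep in 1:10) {
      k <- sample(3:8, 1); ny <- sample(2:6, 1)
      counts <- matrix(stats::rpois(k * ny, 2), nrow = k,
                       dimnames = list(paste0("k", 1:k),
                                       as.character(2000 + seq_len(ny) - 1)))
      storage.mode(counts) <- "integer"
      counts <- counts[rowSums(counts) > 0, , drop = FALSE]
      m <- mat_from_counts(counts, 2000 + seq_len(ncol(counts)) - 1)
      g <- build_cotrend_network(m, min_freq = 1, min_sim = 0.3)
      el <- igraph::as_data_frame(g, what = "edges")
      for (i in seq_len(nrow(el))) {
        expect_equal(el$weight[i],
                     weighted_jaccard(counts[el$from[i], ],
                                      counts[el$to[i], ]))
        expect_gte(el$weight[i], 0.3)
      }
      # threshold monotonicity: stricter thresholds give subgraphs
      g_tight <- build_cotrend_network(m, min_freq = 1, min_sim = 0.6)
      expect_lte(igraph::ecount(g_tight), igraph::ecount(g))
      el_t <- igraph::as_data_frame(g_tight, what = "edges")
      key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
      expect_true(all(key(el_t) %in% key(el)))
      g_freq <- build_cotrend_network(m, min_freq = 5, min_sim = 0.3)
      expect_true(all(igraph::V(g_freq)$name %in% igraph::V(g)$name))
    }
  })
})

test_that("network export/import round-trips in all three formats", {
  counts <- rbind(a = c(4L, 3L, 0L), b = c(8L, 6L, 1L), c = c(0L, 2L, 9L),
                  d = c(9L, 0L, 0L))
  colnames(counts) <- 2000:2002
  m <- mat_from_counts(counts, 2000:2002)
  g <- build_cotrend_network(m, min_freq = 1, min_sim = 0.2)
  expect_gt(igraph::ecount(g), 0)

  for (fmt in c("graphml", "gexf", "edgelist")) {
    f <- tempfile(fileext = paste0(
      ".", switch(fmt, graphml = "graphml", gexf = "gexf",
                  edgelist = "tsv")))
    export_network(g, f, fmt)
    g2 <- import_network(f)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(
      igraph::V(g2)$frequency[order(igraph::V(g2)$name)],
      igraph::V(g)$frequency[order(igraph::V(g)$name)])
    el <- igraph::as_data_frame(g, what = "edges")
    el2 <- igraph::as_data_frame(g2, what = "edges")
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    expect_setequal(key(el2), key(el))
    expect_equal(el2$weight[order(key(el2))], el$weight[order(key(el))],
                 tolerance = 1e-7)
  }

  # a 2-node, 1-edge network with an awkward weight survives exactly enough
  h <- igraph::graph_from_data_frame(
    data.frame(from = "x", to = "y", weight = 0.5714),
    directed = FALSE,
    vertices = data.frame(name = c("x", "y"), frequency = c(101L, 200L)))
  f <- tempfile(fileext = ".graphml")
  export_network(h, f, "graphml")
  expect_equal(igraph::E(import_network(f))$weight, 0.5714,
               tolerance = 1e-6)

  # empty network: valid files with zero nodes
  e <- igraph::graph_from_data_frame(
    data.frame(from = character(0), to = character(0),
               weight = numeric(0)),
    directed = FALSE,
    vertices = data.frame(name = character(0), frequency = integer(0)))
  for (fmt in c("graphml", "gexf", "edgelist")) {
    f <- tempfile(fileext = paste0(".", fmt))
    export_network(e, f, fmt)
    expect_equal(igraph::vcount(import_network(f, fmt)), 0)
  }

  expect_error(export_network(g, tempfile(), "dot"))
})
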