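test_that("to_stochastic adds self-loops and normalizes columns", {
  # single isolated node
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(g1)$name <- "a"
  expect_equal(to_stochastic(g1), matrix(1, 1, 1,
                                         dimnames = list("a", "a")))

  # two nodes, one edge of weight w, unit self-loops: closed form
  w <- 0.6
  g2 <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", weight = w), directed = FALSE)
  M <- to_stochastic(g2)
  expect_equal(M[, "a"], c(a = 1 / (1 + w), b = w / (1 + w)))
  expect_equal(M[, "b"], c(a = w / (1 + w), b = 1 / (1 + w)))

  # columns always sum to one; node order lexicographic
  g3 <- random_weighted_graph(12, 0.4, seed = 3)
  M3 <- to_stochastic(g3)
  expect_equal(unname(colSums(M3)), rep(1, 12), tolerance = 1e-12)
  expect_equal(rownames(M3), sort(igraph::V(g3)$name))

  # "max" and "none" self-loop policies keep columns stochastic
  for (pol in c("max", "none")) {
    Mp <- to_stochastic(g3, mcl_params(self_loops = pol))
    expect_equal(unname(colSums(Mp)), rep(1, 12), tolerance = 1e-12)
  }
})

test_that("mcl_iterate reaches an idempotent stochastic limit", {
  # identity is a fixed point
  I4 <- diag(4)
  dimnames(I4) <- list(letters[1:4], letters[1:4])
  lim <- mcl_iterate(I4, mcl_params())
  expect_equal(unname(lim[, ]), diag(4))
  expect_true(attr(lim, "converged"))

  # 2-node graph with a strong edge: both columns converge to the same
  # attractor pattern (uniform mass over the pair)
  g <- igraph::graph_from_data_frame(
    data.frame(from = "a", to = "b", weight = 0.9), directed = FALSE)
  lim2 <- mcl_iterate(to_stochastic(g), mcl_params())
  expect_equal(matrix(as.numeric(lim2), 2, 2), matrix(0.5, 2, 2),
               tolerance = 1e-4)

  # the limit is idempotent: one more full iteration barely moves it
  g3 <- random_weighted_graph(15, 0.3, seed = 9)
  p <- mcl_params()
  lim3 <- mcl_iterate(to_stochastic(g3), p)
  again <- mcl_iterate(lim3, mcl_params(max_iterations = 1))
  expect_lt(max(abs(again - lim3)), p$convergence_tol * 10)
  expect_equal(unname(colSums(lim3)), rep(1, 15), tolerance = 1e-9)

  # over-aggressive pruning kills a column and is reported
  U <- matrix(1 / 3, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_error(mcl_iterate(U, mcl_params(pruning = 0.9)), "collapsed")
  expect_error(mcl_iterate(matrix(c(1, 1, 0, 1), 2)), "stochastic")
})

test_that("extract_clusters reads partitions off limit matrices", {
  # identity limit: every node a singleton
  I3 <- diag(3)
  dimnames(I3) <- list(c("a", "b", "c"), c("a", "b", "c"))
  cl <- extract_clusters(I3)
  expect_equal(length(cl$clusters), 3)
  expect_equal(unname(cl$labels[c("a", "b", "c")]), 1:3)

  # block-diagonal limit: one cluster per block
  B <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  B[1, 1:2] <- 1
  B[3, 3:4] <- 1
  cl2 <- extract_clusters(B)
  expect_equal(cl2$clusters, list(c("a", "b"), c("c", "d")))
})

test_that("mcl_cluster resolves motif graphs to their natural clusters", {
  params <- mcl_params()
  fx <- small_graph_fixtures()

  # two triangles joined by one weak edge: one cluster per triangle
  cl <- mcl_cluster(fx$bridged_triangles, params)
  expect_equal(cl$clusters, list(c("a", "b", "c"), c("d", "e", "f")))
  expect_true(same_partition(cl$labels, oracle_mcl(fx$bridged_triangles)))

  # two disjoint cliques: exactly the cliques
  cl2 <- mcl_cluster(fx$two_cliques, params)
  expect_equal(cl2$clusters, list(c("a", "b", "c"), c("d", "e", "f")))

  # a fully connected equal-weight triangle: one cluster
  cl3 <- mcl_cluster(fx$triangle, params)
  expect_equal(cl3$clusters, list(c("a", "b", "c")))

  # an isolated node is always its own singleton cluster
  cl4 <- mcl_cluster(fx$clique_plus_isolate, params)
  expect_true(list("d") %in% cl4$clusters || "d" %in% unlist(
    cl4$clusters[lengths(cl4$clusters) == 1]))
})

test_that("MCL clusterings are valid partitions that respect components", {
  params <- mcl_params()
  withr::with_seed(23, {
    for (rep in 1:80) {
      n <- sample(3:25, 1)
      g <- random_weighted_graph(n, stats::runif(1, 0.1, 0.6),
                                 seed = 1000 + rep)
      cl <- mcl_cluster(g, params)
      # exact partition
      expect_setequal(unlist(cl$clusters), igraph::V(g)$name)
      expect_equal(sum(lengths(cl$clusters)), n)
      expect_equal(sort(names(cl$labels)), sort(igraph::V(g)$name))
      # nodes in different graph components never share a cluster
      comp <- igraph::components(g)$membership
      for (cc in cl$clusters) {
        expect_equal(length(unique(comp[cc])), 1)
      }
    }
  })
})

test_that("MCL is equivariant under node permutation", {
  withr::with_seed(41, {
    for (rep in 1:15) {
      g <- random_weighted_graph(sample(4:15, 1), 0.4, seed = 2000 + rep)
      perm <- sample(igraph::vcount(g))
      g_p <- igraph::permute(g, perm)
      expect_true(same_partition(mcl_cluster(g)$labels,
                                 mcl_cluster(g_p)$labels))
    }
  })
})

test_that("MCL agrees with an independent dense-matrix oracle on small graphs", {
  fx <- small_graph_fixtures()
  for (nm in names(fx)) {
    cl <- mcl_cluster(fx[[nm]], mcl_params())
    or <- oracle_mcl(fx[[nm]])
    expect_true(same_partition(cl$labels, or),
                info = paste("fixture:", nm))
  }
})
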